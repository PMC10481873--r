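---
title: "Methods: surrogate-guided genetic screening of herbal combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate-guided genetic screening of herbal combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`herbscreen` implements a two-stage in-silico screen for herbal
combinations. Stage one trains a convolutional classifier (the *surrogate*)
to predict binary treatment efficacy from prescriptions encoded as binary
bag-of-words vectors. Stage two runs a genetic algorithm (GA) over the
combinatorial space of herb subsets, using the trained surrogate's predicted
effectiveness probability inside a size-penalised fitness. This vignette
documents the mathematical conventions, the deliberate design decisions, and
the known limits of each stage.

## Notation and encoding

A vocabulary of $V$ standardized herb names fixes vector positions
(`herb_vocabulary()`, first-occurrence order in `build_vocabulary()`). A
prescription is encoded as $x \in \{0,1\}^V$ with $x_j = 1$ iff herb $j$ is
present. The four-level clinical outcome is recoded to binary efficacy:
complete remission, partial remission and stable map to *effective* (1);
progressive maps to *ineffective* (0).

## The classifier

For a batch of $B$ rows, each input row is treated as a length-$V$,
single-channel 1-D signal. The network is:

1. **Parallel convolution branches** with kernel sizes $1, 3, 5$ (odd sizes
   required), each with $F$ filters, ReLU activation and same-length zero
   padding. Their feature maps are concatenated along the channel axis
   ($3F$ channels).
2. **Second convolution** (kernel 3, $F_2$ filters, ReLU, same padding).
3. **Reduction** to a fixed-length vector — see the pooling discussion below.
4. **Fully connected layers** (sizes 1024 and 512 at full scale, ReLU).
5. **Softmax output** over two classes: class 1 = ineffective, class 2 =
   effective.

Convolutions are lowered to matrix multiplication via `im2col`, with the
position index fastest within a sample, so all heavy arithmetic is BLAS
`dgemm`. Training minimizes the mean cross-entropy with Adam. Predicted
probabilities are clipped to $[10^{-12}, 1]$ inside the loss only, so a
saturated softmax never produces an infinite loss. Class predictions use
argmax with ties broken toward *ineffective* — a deliberate conservative
convention: an undecided network should not recommend a prescription.

### Pooling and position identifiability

With global max pooling after the second convolution, the reduced feature
vector is invariant under any permutation-like relocation of input activity
that preserves local windows: shared convolution weights plus a global max
cannot identify *which* position (herb) was active, only that some local
presence motif occurred somewhere. On binary bag-of-words inputs this is
fatal for the screening application — a surrogate that cannot tell herbs
apart cannot rank herb combinations. Empirically, a global-max model trained
on a noiseless cohort whose label is the presence of one specific herb stalls
at majority-class accuracy, while the flatten variant reaches accuracy 1.0
within a few epochs.

The package therefore defaults to `pooling_mode = "flatten"`, which
concatenates the second convolution's feature maps over all positions and
preserves herb identity. `"global_max"` remains available as a configurable
alternative; it is dramatically cheaper at full scale (the first fully
connected layer sees $F_2$ inputs instead of $V \cdot F_2$) and is adequate
for experiments where only aggregate statistics of the search (such as the
returned combination size) matter.

### Gradient verification

All gradients are analytic and verified against central finite differences
over every parameter (relative $\ell_2$ error below $10^{-6}$ on reduced
networks, for both pooling modes). The in-place Adam kernel is verified to
match a pure-R reference step to $10^{-13}$.

## The genetic algorithm

Individuals are bitstrings $g \in \{0,1\}^V$. The fitness of a combination,
minimized over the search, is

$$ f(g) = \bigl(1 - \hat p_{\text{eff}}(g)\bigr) + \bigl(|g| - N\bigr)^2 $$

where $\hat p_{\text{eff}}$ is the surrogate's predicted effectiveness
probability and $N$ is the target combination size (default 12). Defaults
follow the published search settings: population 10, 1,000 iterations,
5 parents, crossover and mutation rates 0.1, Bernoulli(0.5) initialization,
elitism carrying the single best individual unchanged — which makes the
best-fitness trace non-increasing by construction. Population evaluations
are memoised on the bit pattern, so converged populations cost almost
nothing to score.

### Selection transform

Roulette-wheel selection needs a transform from fitness (lower is better) to
a positive selection weight. Plain inverse fitness $1/f$ degenerates: when
all individuals have large fitness (e.g. early in a run, where the size
penalty dominates), weights become nearly equal and selection pressure
vanishes. The package uses a *windowed quartic* transform

$$ w_i = \frac{1}{4 + (f_i - \min_j f_j)^4} $$

which is invariant under common fitness shifts, gives the incumbent best a
bounded advantage (ratio at most $\approx 1 + \Delta^4/4$ over a competitor
at distance $\Delta$), and intentionally flattens differences below one
fitness unit so that near-optimal variants survive selection. Linear rank
selection was evaluated as an alternative and rejected on measurement: it
was simultaneously too disruptive on a small exhaustively-enumerable
benchmark (oracle agreement collapsed from 17/30 to 1/30 seeds) and too weak
to converge combination size on full-size vocabularies (0/30 vs 21/30).

### Convergence floor under the default operators

With per-individual mutation at rate 0.1, a generation produces on average
only $0.9$ single-bit flips across nine offspring. From a Bernoulli(0.5)
start on a 334-herb vocabulary, 1,000 iterations reliably drive the size
penalty near zero, but the final polish to *exactly* the target size is
stochastic: roughly half to three quarters of seeds end at the exact target,
with the misses scattered one to a few bits above. The *modal* size over ten
seeds is therefore a robust statistic (the expected value is the target
size), while any single seed is not. Likewise, identity-level hill-climbing
(swapping a filler herb for a core herb, which requires two coordinated
flips) is essentially unreachable under the default per-individual operator;
`mutation = "per_bit"` at the classic $1/V$ rate performs such swaps in a
single mutation and is the recommended setting when combination *identity*,
not just size, matters.

## The synthetic cohort generator

Real prescription cohorts are not redistributable, so validation uses
synthetic cohorts with a planted signal. Each record draws a formula size
(8–16 by default), includes each of the 12 *core* herbs independently with
probability `core_rate`, fills the remainder with structured filler herbs
(drawn in small co-occurring blocks, mimicking herb-pair conventions), and
labels the record effective with probability

$$ p = \operatorname{logit}^{-1}(\beta_0 + \beta_1 k), $$

where $k$ is the number of core herbs present, followed by symmetric label
noise. The default intercept is calibrated by root-finding so the expected
ineffective fraction matches the published cohort's class balance
(128 of 745). `calibrate_intercept()` re-runs this calibration for custom
specifications.

Two generator regimes matter in practice:

* **Near-zero-centred transition** (default): realistic class balance, but
  probability gains beyond a few core herbs are below $10^{-3}$ and drown in
  the surrogate's off-manifold extrapolation noise. Full identity recovery
  is *not* an achievable property in this regime — a fact verified with a
  greedy steepest-descent oracle, which bounds any local search from above
  and still scores at chance.
* **Centred transition** (e.g. intercept $-12$, effect $2$, core rate
  $0.5$): the logistic transition sits inside the observed core-count band,
  training data span it, and per-herb gains stay macroscopic up to the
  overlap at which the Jaccard index against the planted core crosses 0.5.
  In this regime the full pipeline recovers the planted combination in most
  seeds, and recovery quality is surrogate-limited (the GA matches the
  greedy oracle seed-for-seed).

`recovery_score()` reports the Jaccard index between the found and planted
combinations.

## Determinism and provenance

Every stochastic routine takes an explicit seed and restores the caller's
RNG state. Stage seeds are derived from one master seed with fixed offsets.
All CLI artifacts (TSV/CSV/JSON) embed the md5 hash of the resolved run
configuration and every seed in play, and identical configurations reproduce
outputs byte for byte. Model checkpoints round-trip parameters losslessly
through JSON.

## Problem sizes and cost

The full-scale default (745 × 334 cohort, 128-filter branches, 1024/512
fully connected, flatten pooling) trains at roughly 40–60 s per epoch on one
CPU with single-threaded BLAS; the global-max variant is roughly four times
faster. GA runs cost seconds: the surrogate forward pass over a population
of 10 dominates, and memoisation removes most of it once the population
converges.

## Limitations

* The surrogate is trained on observational prescriptions; its probabilities
  off the data manifold (arbitrary 12-herb subsets) are extrapolations, and
  search quality is bounded by what the surrogate encodes.
* The GA defaults reproduce the published search behaviour, including its
  limited exploration budget; they are not tuned for identity recovery (see
  the per-bit mutation note above).
* Synthetic cohorts use an additive logistic signal in core-herb count; they
  do not model herb-herb interactions beyond filler co-occurrence blocks.
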