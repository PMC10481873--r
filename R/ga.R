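# Genetic algorithm over herb bitstrings.
#
# Each individual is a binary vector over the vocabulary: bit j set means herb
# j is in the candidate combination. The fitness to be MINIMISED is
#
#     fitness(X) = P(ineffective | X) + (sum(X) - N)^2
#
# where P(ineffective | X) = 1 - scorer(X) comes from the trained classifier
# and N is the target number of herbs. The squared term dominates until the
# combination size settles at N; the probability term then drives the search
# toward combinations the surrogate scores as effective — the two-phase
# convergence characteristic of this fitness.
#
# Because lower fitness is better, roulette-wheel selection transforms fitness
# into selection weights. The default "windowed" transform is
#
#     w_i = 1 / (knee + (fitness_i - min(fitness))^4)
#
# Windowing (subtracting the population minimum) keeps selection pressure
# meaningful even when all fitness values are large, where the plain inverse
# 1/(fitness + eps) degenerates to near-uniform sampling and the search
# stalls. The quartic with knee = 4 places the transition between the two
# scales this fitness mixes: individuals within ~1 fitness unit of the best
# (probability-term differences, and the size-adjacent intermediates that
# two-flip herb swaps must pass through) remain selectable at comparable
# probability, while individuals more than one size-penalty rung behind are
# effectively excluded. Plain inverse and rank weighting remain available as
# alternatives. Exactly one elite (the global best) is carried forward
# unchanged each generation, which makes the best-fitness trace
# non-increasing.

#' Genetic-algorithm configuration
#'
#' Defaults follow the published search settings: population of 10, 1,000
#' iterations, 5 parents per generation by roulette selection, crossover and
#' mutation rates of 0.1, and a target combination size of 12 herbs.
#'
#' @param population_size Individuals per generation (default 10).
#' @param max_iterations Generations to run (default 1000).
#' @param n_parents Parents selected per generation (default 5; must not
#'   exceed `population_size`).
#' @param crossover_rate Per-position swap probability of uniform crossover
#'   (default 0.1); under `crossover = "single_point"`, the probability that a
#'   parent pair is crossed at one random point.
#' @param mutation_rate Probability that an offspring has one uniformly chosen
#'   bit flipped (default 0.1); under `mutation = "per_bit"`, the independent
#'   flip probability of every bit.
#' @param target_size Target number of herbs N in the size penalty
#'   (default 12).
#' @param seed Integer seed; identical seeds give identical traces.
#' @param init_density Bernoulli probability of each initial bit (default 0.5).
#' @param selection Roulette weighting: `"windowed"` (default) uses
#'   `1/(4 + (fitness - min(fitness))^4)`; `"inverse"` uses
#'   `1/(fitness + eps)`; `"rank"` uses reversed fitness ranks. See
#'   [roulette_select()].
#' @param crossover `"uniform"` (default) or `"single_point"`.
#' @param mutation `"per_individual"` (default) or `"per_bit"`.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 10L, max_iterations = 1000L,
                      n_parents = 5L, crossover_rate = 0.1,
                      mutation_rate = 0.1, target_size = 12L, seed = 1L,
                      init_density = 0.5,
                      selection = c("windowed", "inverse", "rank"),
                      crossover = c("uniform", "single_point"),
                      mutation = c("per_individual", "per_bit")) {
  cfg <- list(population_size = as.integer(population_size),
              max_iterations = as.integer(max_iterations),
              n_parents = as.integer(n_parents),
              crossover_rate = as.numeric(crossover_rate),
              mutation_rate = as.numeric(mutation_rate),
              target_size = as.integer(target_size),
              seed = as.integer(seed),
              init_density = as.numeric(init_density),
              selection = match.arg(selection),
              crossover = match.arg(crossover),
              mutation = match.arg(mutation))
  if (cfg$population_size < 2L) stopf("population_size must be at least 2")
  if (cfg$n_parents < 1L || cfg$n_parents > cfg$population_size) {
    stopf("n_parents must be in [1, population_size]")
  }
  rates <- c(cfg$crossover_rate, cfg$mutation_rate, cfg$init_density)
  if (any(rates < 0) || any(rates > 1)) stopf("rates must lie in [0, 1]")
  if (cfg$target_size < 1L) stopf("target_size must be at least 1")
  if (cfg$max_iterations < 1L) stopf("max_iterations must be at least 1")
  structure(cfg, class = "ga_config")
}

#' Size-penalised fitness of herb combinations
#'
#' `fitness(X) = (1 - scorer(X)) + (sum(X) - N)^2`, minimised by the search:
#' the first term is the surrogate's predicted ineffectiveness probability,
#' the second a squared penalty on deviating from the target size N.
#'
#' @param genes Binary vector, or matrix with one individual per row.
#' @param scorer Function mapping a binary matrix (rows = combinations) to
#'   `P(effective)` values in `[0, 1]`, e.g. [ndcnn_scorer()].
#' @param target_size Target herb count N.
#' @return Numeric vector of non-negative fitness values (lower is better).
#' @export
combination_fitness <- function(genes, scorer, target_size) {
  X <- if (is.null(dim(genes))) matrix(genes, nrow = 1L) else as.matrix(genes)
  p <- as.numeric(scorer(X))
  if (length(p) != nrow(X)) {
    stopf("scorer returned %d values for %d combinations", length(p), nrow(X))
  }
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stopf("scorer must return probabilities in [0, 1]")
  }
  (1 - p) + (rowSums(X) - target_size)^2
}

#' Wrap a trained classifier as a GA scorer
#'
#' @param model A trained `ndcnn_model`.
#' @return A function mapping a binary matrix to `P(effective)` per row.
#' @export
ndcnn_scorer <- function(model) {
  stopifnot(inherits(model, "ndcnn_model"))
  function(X) predict_effective_prob(model, X)
}

#' Initialise a GA population
#'
#' Each of the `population_size` individuals draws every bit independently
#' from Bernoulli(`init_density`), using the configured seed.
#'
#' @param config A [ga_config()].
#' @param vocab_size Number of herbs (gene-vector length); must be at least
#'   `config$target_size`.
#' @return Integer 0/1 matrix, one individual per row.
#' @export
init_population <- function(config, vocab_size) {
  stopifnot(inherits(config, "ga_config"))
  vocab_size <- as.integer(vocab_size)
  if (vocab_size < config$target_size) {
    stopf("vocabulary size %d is smaller than target combination size %d",
          vocab_size, config$target_size)
  }
  with_seed(derive_seed(config$seed, 0L), {
    matrix(stats::rbinom(config$population_size * vocab_size, 1L,
                         config$init_density),
           nrow = config$population_size)
  })
}

#' Roulette-wheel selection for minimisation
#'
#' Samples parent indices with replacement. The classical roulette wheel
#' favours *large* values, so fitness (lower = better) is transformed into a
#' selection weight first:
#'
#' * `"windowed"` (default): `1 / (knee + (fitness - min(fitness))^4)`.
#'   Windowing on the population minimum keeps pressure meaningful at every
#'   fitness scale, and the quartic knee separates the two scales the
#'   size-penalised fitness mixes: individuals within about one fitness unit
#'   of the best (probability differences, size-adjacent intermediates) stay
#'   selectable at comparable probability, while individuals more than one
#'   size-penalty rung behind are effectively excluded. Equal fitness values
#'   yield uniform selection.
#' * `"inverse"`: `1 / (fitness + eps)`. When all fitness values are large
#'   (e.g. under a dominant size penalty) the weights become nearly equal and
#'   selection pressure vanishes, which stalls convergence.
#' * `"rank"`: reversed fitness rank (best gets the largest weight).
#'
#' Uses the current RNG stream.
#'
#' @param fitness Numeric vector of evaluated fitness values (lower = better).
#' @param n_parents Number of parents to draw.
#' @param selection Weighting scheme.
#' @param eps Inverse-transform offset guarding against division by zero
#'   (default 1e-6).
#' @param knee Windowed-transform constant (default 4): fitness gaps below
#'   `knee^(1/4)` (about 1.4) cost little selection probability, gaps above it
#'   are suppressed quartically.
#' @return Integer vector of selected indices (length `n_parents`).
#' @export
roulette_select <- function(fitness, n_parents,
                            selection = c("windowed", "inverse", "rank"),
                            eps = 1e-6, knee = 4) {
  selection <- match.arg(selection)
  if (length(fitness) == 0L) stopf("cannot select from an empty population")
  w <- switch(selection,
              windowed = 1 / (knee + (fitness - min(fitness))^4),
              inverse = 1 / (fitness + eps),
              rank = rank(-fitness, ties.method = "average"))
  sample.int(length(fitness), n_parents, replace = TRUE, prob = w)
}

#' Uniform crossover of two parent bitstrings
#'
#' Each position is independently swapped between the two children with
#' probability `rate`. With `method = "single_point"`, the pair is instead
#' crossed at one uniformly chosen cut point with probability `rate` and left
#' untouched otherwise. Uses the current RNG stream.
#'
#' @param parent_a,parent_b Equal-length binary vectors.
#' @param rate Crossover rate.
#' @param method `"uniform"` (default) or `"single_point"`.
#' @return List with binary vectors `child_a`, `child_b`.
#' @export
ga_crossover <- function(parent_a, parent_b, rate,
                         method = c("uniform", "single_point")) {
  method <- match.arg(method)
  if (length(parent_a) != length(parent_b)) {
    stopf("parents have different gene lengths (%d vs %d)",
          length(parent_a), length(parent_b))
  }
  L <- length(parent_a)
  child_a <- parent_a
  child_b <- parent_b
  if (method == "uniform") {
    swap <- stats::runif(L) < rate
    child_a[swap] <- parent_b[swap]
    child_b[swap] <- parent_a[swap]
  } else if (stats::runif(1L) < rate && L > 1L) {
    cut <- sample.int(L - 1L, 1L)
    tail_idx <- (cut + 1L):L
    child_a[tail_idx] <- parent_b[tail_idx]
    child_b[tail_idx] <- parent_a[tail_idx]
  }
  list(child_a = child_a, child_b = child_b)
}

#' Mutate an offspring bitstring
#'
#' Default (`"per_individual"`): with probability `rate` exactly one uniformly
#' chosen bit is flipped (0 becomes 1 or 1 becomes 0); otherwise the
#' individual is returned unchanged. `"per_bit"`: every bit flips
#' independently with probability `rate`. Uses the current RNG stream.
#'
#' @param genes Binary vector.
#' @param rate Mutation rate.
#' @param method `"per_individual"` (default) or `"per_bit"`.
#' @return Mutated binary vector.
#' @export
ga_mutate <- function(genes, rate, method = c("per_individual", "per_bit")) {
  method <- match.arg(method)
  if (method == "per_individual") {
    if (stats::runif(1L) < rate) {
      j <- sample.int(length(genes), 1L)
      genes[j] <- 1L - genes[j]
    }
  } else {
    flip <- stats::runif(length(genes)) < rate
    genes[flip] <- 1L - genes[flip]
  }
  genes
}

# Evaluate a population matrix with memoisation: converged populations contain
# many repeated individuals, so scoring is cached on the set-bit signature.
eval_population <- function(pop, scorer, target_size, cache) {
  keys <- paste0("k", apply(pop, 1L, function(g) paste(which(g == 1L),
                                                       collapse = ",")))
  fit <- rep(NA_real_, nrow(pop))
  hit <- vapply(keys, function(k) !is.null(cache[[k]]) , logical(1L))
  fit[hit] <- vapply(keys[hit], function(k) cache[[k]], numeric(1L))
  miss <- which(!hit)
  if (length(miss)) {
    # score each distinct missing pattern once, even within one generation
    first <- miss[!duplicated(keys[miss])]
    fresh <- combination_fitness(pop[first, , drop = FALSE], scorer,
                                 target_size)
    for (i in seq_along(first)) cache[[keys[first[i]]]] <- fresh[i]
    fit[miss] <- vapply(keys[miss], function(k) cache[[k]], numeric(1L))
  }
  fit
}

#' Evolve the best herb combination
#'
#' Runs `max_iterations` generations. Each generation: evaluate the
#' population, update and record the global best, select `n_parents` parents
#' by roulette, refill the population with `population_size - 1` offspring
#' produced by pairwise crossover and mutation of randomly paired parents, and
#' carry the global best forward unchanged (elitism of one). Fitness values
#' are memoised across generations, so repeated individuals are scored once.
#'
#' @param scorer Function mapping a binary matrix to `P(effective)` per row
#'   (see [ndcnn_scorer()]).
#' @param config A [ga_config()].
#' @param vocab A [herb_vocabulary()], or an integer vocabulary size.
#' @param verbose Print progress every 100 iterations (default FALSE).
#' @return List of class `ga_result`:
#'   * `best`: list with `genes`, `fitness`, `size`, `p_effective`;
#'   * `trace`: data frame (`iteration`, `best_fitness`, `mean_fitness`,
#'     `best_size`), one row per iteration, `best_fitness` non-increasing;
#'   * `population_fitness`: iterations x population matrix;
#'   * `best_snapshots`: data frame of iterations at which the global best
#'     improved, with its fitness;
#'   * `config`: the configuration used.
#' @export
ga_evolve <- function(scorer, config, vocab, verbose = FALSE) {
  stopifnot(inherits(config, "ga_config"))
  vocab_size <- if (inherits(vocab, "herb_vocabulary")) length(vocab)
                else as.integer(vocab)
  pop <- init_population(config, vocab_size)
  cache <- new.env(parent = emptyenv())
  n_iter <- config$max_iterations
  trace <- data.frame(iteration = seq_len(n_iter), best_fitness = NA_real_,
                      mean_fitness = NA_real_, best_size = NA_integer_)
  pop_fit <- matrix(NA_real_, n_iter, config$population_size)
  snap_it <- integer()
  snap_fit <- numeric()
  best_genes <- NULL
  best_fit <- Inf

  with_seed(derive_seed(config$seed, 1L), {
    fit <- eval_population(pop, scorer, config$target_size, cache)
    for (it in seq_len(n_iter)) {
      i_min <- which.min(fit)
      if (fit[i_min] < best_fit) {
        best_fit <- fit[i_min]
        best_genes <- pop[i_min, ]
        snap_it <- c(snap_it, it)
        snap_fit <- c(snap_fit, best_fit)
      }
      trace$best_fitness[it] <- best_fit
      trace$mean_fitness[it] <- mean(fit)
      trace$best_size[it] <- sum(best_genes)
      pop_fit[it, ] <- fit
      if (verbose && it %% 100L == 0L) {
        message(sprintf("iteration %4d: best fitness %.4f (size %d)",
                        it, best_fit, sum(best_genes)))
      }
      if (it == n_iter) break

      parents <- pop[roulette_select(fit, config$n_parents,
                                     config$selection), , drop = FALSE]
      n_off <- config$population_size - 1L
      offspring <- matrix(0L, n_off, vocab_size)
      filled <- 0L
      while (filled < n_off) {
        pair <- sample.int(nrow(parents), 2L, replace = TRUE)
        ch <- ga_crossover(parents[pair[1L], ], parents[pair[2L], ],
                           config$crossover_rate, config$crossover)
        for (child in list(ch$child_a, ch$child_b)) {
          if (filled >= n_off) break
          filled <- filled + 1L
          offspring[filled, ] <- ga_mutate(child, config$mutation_rate,
                                           config$mutation)
        }
      }
      pop <- rbind(best_genes, offspring)
      fit <- eval_population(pop, scorer, config$target_size, cache)
    }
  })

  structure(list(
    best = list(genes = best_genes, fitness = best_fit,
                size = sum(best_genes),
                p_effective = 1 - (best_fit - (sum(best_genes) -
                                                 config$target_size)^2)),
    trace = trace,
    population_fitness = pop_fit,
    best_snapshots = data.frame(iteration = snap_it, best_fitness = snap_fit),
    config = config), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result> best fitness %.4f | %d herbs | P(effective) = %.3f | %d iterations\n",
    x$best$fitness, x$best$size, x$best$p_effective,
    nrow(x$trace)))
  invisible(x)
}

#' Decode the best individual to herb names
#'
#' @param best A `ga_result`, or a list/vector with the gene bitstring.
#' @param vocab A [herb_vocabulary()].
#' @param scorer Optional scorer used to (re)compute `P(effective)`.
#' @return List with `herbs` (names of set bits, vocabulary order), `indices`
#'   (1-based positions), and `p_effective` (if a scorer is supplied or the
#'   input is a `ga_result`).
#' @export
decode_combination <- function(best, vocab, scorer = NULL) {
  genes <- if (inherits(best, "ga_result")) best$best$genes
           else if (is.list(best)) best$genes
           else best
  herbs <- decode_prescription(genes, vocab)
  p <- if (!is.null(scorer)) {
    as.numeric(scorer(matrix(genes, nrow = 1L)))
  } else if (inherits(best, "ga_result")) {
    best$best$p_effective
  }
  list(herbs = herbs, indices = which(genes != 0), p_effective = p)
}

#' Export a search trace as CSV
#'
#' Columns `iteration`, `best_fitness`, `mean_fitness`, `best_size` — the data
#' behind fitness-convergence curves.
#'
#' @param result A `ga_result` (or its `trace` data frame).
#' @param path File path.
#' @param header_lines Optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path, header_lines = character()) {
  trace <- if (inherits(result, "ga_result")) result$trace else result
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.csv(trace, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
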