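Package: herbscreen
Title: Surrogate-Guided Genetic Screening of Herbal Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage in-silico screening of traditional Chinese medicine
    (TCM) herb combinations for liver-cancer prescriptions. Prescriptions are
    encoded as binary bag-of-words vectors over a fixed herb vocabulary and a
    multi-scale one-dimensional convolutional classifier (parallel kernels of
    sizes 1/3/5 whose feature maps are concatenated and convolved again) is
    trained to predict treatment efficacy. A genetic algorithm with roulette
    selection, uniform crossover, point mutation and elitism then searches the
    combinatorial herb space for the combination the trained classifier scores
    best under a size-penalised fitness. Includes a synthetic-cohort generator
    with a planted effective core so that the full pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
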