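# Genetic algorithm: operators, fitness, memoisation, evolution invariants,
# exhaustive-oracle agreement on a small vocabulary.

test_that("ga_config defaults follow the published search settings", {
  cfg <- ga_config()
  expect_identical(cfg$population_size, 10L)
  expect_identical(cfg$max_iterations, 1000L)
  expect_identical(cfg$n_parents, 5L)
  expect_equal(cfg$crossover_rate, 0.1)
  expect_equal(cfg$mutation_rate, 0.1)
  expect_identical(cfg$target_size, 12L)
})

test_that("ga_config validates its ranges", {
  expect_error(ga_config(population_size = 1L), "at least 2")
  expect_error(ga_config(n_parents = 11L), "n_parents")
  expect_error(ga_config(crossover_rate = 1.2), "rates")
  expect_error(ga_config(target_size = 0L), "target_size")
  expect_error(ga_config(max_iterations = 0L), "max_iterations")
})

test_that("combination_fitness equals its formula", {
  scorer <- function(X) rep(0.75, nrow(X))
  g <- c(1L, 1L, 0L, 1L)  # size 3
  expect_equal(combination_fitness(g, scorer, 3L), 0.25)
  expect_equal(combination_fitness(g, scorer, 5L), 0.25 + 4)
  X <- rbind(c(1, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(combination_fitness(X, scorer, 2L), c(0.25 + 1, 0.25 + 4))
  expect_error(combination_fitness(g, function(X) 2, 3L), "probabilities")
  expect_error(combination_fitness(X, function(X) 0.5, 3L), "returned 1 values")
})

test_that("init_population is Bernoulli(init_density) and reproducible", {
  cfg <- ga_config(seed = 4L, init_density = 0.3)
  pop <- init_population(cfg, 500L)
  expect_identical(dim(pop), c(10L, 500L))
  expect_true(all(pop %in% 0:1))
  expect_lt(abs(mean(pop) - 0.3), 0.03)  # 5000 draws, sd ~ 0.0065
  expect_identical(pop, init_population(cfg, 500L))
  expect_error(init_population(ga_config(target_size = 12L), 5L),
               "smaller than target")
})

test_that("uniform crossover swaps positions at the configured rate", {
  a <- rep(1L, 2000L)
  b <- rep(0L, 2000L)
  ch <- herbscreen:::with_seed(1L, ga_crossover(a, b, 0.1))
  swapped <- sum(ch$child_a == 0L)
  expect_identical(which(ch$child_a == 0L), which(ch$child_b == 1L))
  expect_gt(swapped, 140L)  # Binomial(2000, 0.1): mean 200, sd ~13.4
  expect_lt(swapped, 260L)
  ch0 <- ga_crossover(a, b, 0)
  expect_identical(ch0$child_a, a)
  expect_identical(ch0$child_b, b)
  expect_error(ga_crossover(a, b[-1L], 0.1), "different gene lengths")
})

test_that("single-point crossover exchanges one tail", {
  a <- rep(1L, 20L)
  b <- rep(0L, 20L)
  ch <- herbscreen:::with_seed(2L, ga_crossover(a, b, 1, "single_point"))
  d <- which(ch$child_a != a)
  expect_true(length(d) >= 1L && all(diff(d) == 1L) && max(d) == 20L)
  expect_identical(ch$child_b[d], a[d])
})

test_that("per-individual mutation flips at most one bit at the given rate", {
  g <- rep(0L, 50L)
  flips <- herbscreen:::with_seed(7L, {
    vapply(1:2000, function(i) sum(ga_mutate(g, 0.1) != g), 0L)
  })
  expect_true(all(flips %in% 0:1))
  expect_gt(mean(flips), 0.07)  # Binomial(2000, 0.1) / 2000
  expect_lt(mean(flips), 0.13)
  expect_identical(ga_mutate(g, 0), g)
})

test_that("per-bit mutation flips each bit independently", {
  g <- rep(0L, 5000L)
  mutated <- herbscreen:::with_seed(8L, ga_mutate(g, 0.1, "per_bit"))
  frac <- mean(mutated != g)
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.12)
})

test_that("roulette_select favours lower fitness and handles ties", {
  fit <- c(0.1, 5, 5, 5, 5)
  idx <- herbscreen:::with_seed(3L, roulette_select(fit, 2000L))
  expect_gt(mean(idx == 1L), 0.5)  # best dominates under windowed weights
  # equal fitness: uniform selection
  idx2 <- herbscreen:::with_seed(3L, roulette_select(rep(7, 4L), 2000L))
  expect_true(all(abs(tabulate(idx2, 4L) / 2000 - 0.25) < 0.05))
  expect_error(roulette_select(numeric(), 1L), "empty population")
})

test_that("selection pressure survives large absolute fitness (windowed)", {
  # both individuals are far from zero; windowed must still prefer the better
  fit <- c(100, 102)
  idx <- herbscreen:::with_seed(5L, roulette_select(fit, 1000L, "windowed"))
  expect_gt(mean(idx == 1L), 0.7)
  # plain inverse degenerates to a coin flip in the same situation
  idx2 <- herbscreen:::with_seed(5L, roulette_select(fit, 1000L, "inverse"))
  expect_lt(abs(mean(idx2 == 1L) - 0.5), 0.05)
})

test_that("population evaluation memoises repeated individuals", {
  calls <- 0L
  scorer <- function(X) { calls <<- calls + nrow(X); rep(0.5, nrow(X)) }
  cache <- new.env(parent = emptyenv())
  pop <- rbind(c(1L, 0L, 1L), c(1L, 0L, 1L), c(0L, 1L, 1L))
  f1 <- herbscreen:::eval_population(pop, scorer, 2L, cache)
  expect_identical(calls, 2L)  # two distinct rows
  f2 <- herbscreen:::eval_population(pop, scorer, 2L, cache)
  expect_identical(calls, 2L)  # all cached
  expect_identical(f1, f2)
  expect_equal(f1, c(0.5 + 0, 0.5 + 0, 0.5 + 0), tolerance = 1e-12)
})

test_that("ga_evolve returns a consistent, reproducible result object", {
  scorer <- function(X) stats::plogis(rowSums(X) - 3)
  cfg <- ga_config(seed = 6L, max_iterations = 50L, target_size = 3L)
  r1 <- ga_evolve(scorer, cfg, 20L)
  r2 <- ga_evolve(scorer, cfg, 20L)
  expect_s3_class(r1, "ga_result")
  expect_identical(r1$best$genes, r2$best$genes)
  expect_identical(r1$trace, r2$trace)
  expect_identical(nrow(r1$trace), 50L)
  expect_identical(dim(r1$population_fitness), c(50L, 10L))
  # elitism: best fitness trace is non-increasing
  expect_true(all(diff(r1$trace$best_fitness) <= 0))
  # the reported best matches an independent fitness computation
  expect_equal(r1$best$fitness,
               combination_fitness(r1$best$genes, scorer, 3L))
  expect_identical(r1$best$size, sum(r1$best$genes))
  # snapshots are the improvement points of the trace
  expect_true(all(r1$best_snapshots$iteration %in% r1$trace$iteration))
  expect_identical(min(r1$best_snapshots$best_fitness),
                   r1$trace$best_fitness[50L])
})

test_that("ga_evolve matches exhaustive enumeration on a tiny vocabulary", {
  # 6-herb vocabulary: 64 subsets, enumerable
  coefs <- c(1.5, -0.8, 0.9, -1.2, 0.4, 2.0)
  scorer <- function(X) stats::plogis(as.numeric(X %*% coefs) - 0.5)
  subsets <- as.matrix(expand.grid(rep(list(0:1), 6L)))
  oracle <- min(combination_fitness(subsets, scorer, 3L))
  hits <- vapply(1:10, function(s) {
    r <- ga_evolve(scorer, ga_config(seed = s, max_iterations = 300L,
                                     target_size = 3L), 6L)
    isTRUE(all.equal(r$best$fitness, oracle))
  }, logical(1L))
  expect_gte(sum(hits), 9L)
})

test_that("decode_combination names the selected herbs", {
  vocab <- herb_vocabulary(c("a", "b", "c", "d", "e"))
  genes <- c(0L, 1L, 0L, 1L, 0L)
  d <- decode_combination(genes, vocab)
  expect_identical(d$herbs, c("b", "d"))
  expect_identical(d$indices, c(2L, 4L))
  d2 <- decode_combination(genes, vocab, scorer = function(X) 0.9)
  expect_equal(d2$p_effective, 0.9)
})

test_that("trace CSV round-trips with provenance comments", {
  scorer <- function(X) rep(0.5, nrow(X))
  r <- ga_evolve(scorer, ga_config(seed = 2L, max_iterations = 5L,
                                   target_size = 2L), 8L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(r, path, header_lines = "# seed: 2")
  expect_identical(readLines(path)[1L], "# seed: 2")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$best_fitness, r$trace$best_fitness)
})
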