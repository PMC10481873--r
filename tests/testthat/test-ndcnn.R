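# Classifier: config validation, initialisation, forward oracle, gradients,
# optimizer equivalence, training loop invariants, evaluation.

test_that("ndcnn_config defaults follow the published architecture", {
  cfg <- ndcnn_config()
  expect_identical(cfg$input_dim, 334L)
  expect_identical(cfg$branch_kernel_sizes, c(1L, 3L, 5L))
  expect_identical(cfg$branch_filters, 128L)
  expect_identical(cfg$second_kernel_size, 3L)
  expect_identical(cfg$second_filters, 128L)
  expect_identical(cfg$fc_sizes, c(1024L, 512L))
  expect_identical(cfg$output_size, 2L)
  expect_identical(cfg$epochs, 25L)
  expect_identical(cfg$batch_size, 32L)
  expect_equal(cfg$learning_rate, 1e-3)
})

test_that("ndcnn_config rejects invalid settings", {
  expect_error(ndcnn_config(branch_kernel_sizes = c(2L, 3L)), "odd")
  expect_error(ndcnn_config(second_kernel_size = 4L), "odd")
  expect_error(ndcnn_config(output_size = 3L), "output_size")
  expect_error(ndcnn_config(learning_rate = 0), "learning_rate")
  expect_error(ndcnn_config(branch_filters = 0L), "positive")
})

test_that("initialisation is seed-deterministic with correct shapes", {
  m1 <- make_tiny_model(seed = 3L)
  m2 <- make_tiny_model(seed = 3L)
  m3 <- make_tiny_model(seed = 4L)
  f <- herbscreen:::flatten_params
  expect_identical(f(m1$params), f(m2$params))
  expect_false(identical(f(m1$params), f(m3$params)))
  cfg <- m1$config
  expect_identical(dim(m1$params$branches[[2L]]$W),
                   c(cfg$branch_kernel_sizes[2L] * 1L, cfg$branch_filters))
  c_in <- length(cfg$branch_kernel_sizes) * cfg$branch_filters
  expect_identical(dim(m1$params$conv2$W),
                   c(cfg$second_kernel_size * c_in, cfg$second_filters))
  expect_identical(dim(m1$params$fc[[1L]]$W),
                   c(cfg$input_dim * cfg$second_filters, cfg$fc_sizes[1L]))
  expect_true(all(is.finite(f(m1$params))))
})

test_that("forward pass matches the straight-line reference (both poolings)", {
  for (pooling in c("flatten", "global_max")) {
    model <- make_tiny_model(seed = 11L, pooling_mode = pooling)
    set.seed(42)
    X <- matrix(rbinom(3L * 12L, 1L, 0.4), 3L, 12L)
    probs <- ndcnn_forward(model, X)
    for (r in 1:3) {
      expect_equal(unname(probs[r, ]), ref_forward_one(model, X[r, ]),
                   tolerance = 1e-12)
    }
    expect_equal(unname(rowSums(probs)), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("forward pass with workspace equals forward pass without", {
  model <- make_tiny_model(seed = 2L)
  set.seed(7)
  X <- matrix(rbinom(5L * 12L, 1L, 0.5), 5L, 12L)
  storage.mode(X) <- "double"
  ws <- herbscreen:::train_workspace(model$config, model$params, 5L)
  p1 <- herbscreen:::nd_forward(model, X)$probs
  p2 <- herbscreen:::nd_forward(model, X, ws = ws)$probs
  expect_identical(p1, p2)
})

test_that("single vectors and non-binary input are handled", {
  model <- make_tiny_model()
  p <- ndcnn_forward(model, rep(c(1, 0), 6))
  expect_identical(dim(p), c(1L, 2L))
  expect_warning(ndcnn_forward(model, matrix(0.5, 1L, 12L)), "not binary")
  expect_error(ndcnn_forward(model, matrix(1, 1L, 9L)), "expects")
})

test_that("cross_entropy matches its formula and clips", {
  pred <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  targ <- rbind(c(1, 0), c(0, 1))
  expect_equal(cross_entropy(pred, targ),
               -mean(c(log(0.8), log(0.7))))
  # clipping keeps exact-zero predictions finite
  expect_true(is.finite(cross_entropy(rbind(c(0, 1)), rbind(c(1, 0)))))
  expect_error(cross_entropy(pred, targ[1L, , drop = FALSE]), "targets are")
})

test_that("analytic gradients match central finite differences", {
  for (pooling in c("flatten", "global_max")) {
    model <- make_tiny_model(seed = 5L, pooling_mode = pooling)
    # jitter parameters off the ReLU kinks: freshly initialised biases are 0,
    # which puts zero-window pre-activations exactly at relu(0), where the
    # two-sided difference quotient is not the subgradient used analytically
    set.seed(99)
    model$params <- herbscreen:::param_map(
      function(x) x + stats::rnorm(length(x), 0, 0.05), model$params)
    set.seed(13)
    X <- matrix(rbinom(4L * 12L, 1L, 0.4), 4L, 12L)
    storage.mode(X) <- "double"
    targets <- herbscreen:::one_hot(c(0L, 1L, 1L, 0L))
    bk <- herbscreen:::nd_backward(model, X, targets)
    g_ana <- herbscreen:::flatten_params(bk$grads)
    g_fd <- ref_fd_gradient(model, X, targets)
    rel <- sqrt(sum((g_ana - g_fd)^2)) / (sqrt(sum(g_fd^2)) + 1e-12)
    expect_lt(rel, 1e-6)
  }
})

test_that("gradients with workspace equal gradients without", {
  model <- make_tiny_model(seed = 8L)
  set.seed(3)
  X <- matrix(rbinom(4L * 12L, 1L, 0.4), 4L, 12L)
  storage.mode(X) <- "double"
  targets <- herbscreen:::one_hot(c(1L, 0L, 1L, 1L))
  ws <- herbscreen:::train_workspace(model$config, model$params, 4L)
  g1 <- herbscreen:::nd_backward(model, X, targets)
  g2 <- herbscreen:::nd_backward(model, X, targets, ws = ws)
  expect_equal(herbscreen:::flatten_params(g1$grads),
               herbscreen:::flatten_params(g2$grads), tolerance = 1e-14)
  expect_identical(g1$loss, g2$loss)
})

test_that("in-place Adam matches the pure-R reference step", {
  model <- make_tiny_model(seed = 21L)
  set.seed(99)
  X <- matrix(rbinom(4L * 12L, 1L, 0.5), 4L, 12L)
  storage.mode(X) <- "double"
  targets <- herbscreen:::one_hot(c(0L, 1L, 0L, 1L))
  bk <- herbscreen:::nd_backward(model, X, targets)
  # reference
  st_ref <- herbscreen:::adam_init(model$params)
  ref <- herbscreen:::adam_step(model$params, bk$grads, st_ref, 1e-3)
  # in-place on private copies
  p2 <- herbscreen:::param_map(function(x) x + 0, model$params)
  st2 <- herbscreen:::adam_init(p2)
  herbscreen:::adam_update_inplace(p2, bk$grads, st2$m, st2$v, 1e-3, 1L)
  expect_equal(herbscreen:::flatten_params(p2),
               herbscreen:::flatten_params(ref$params), tolerance = 1e-13)
  expect_equal(herbscreen:::flatten_params(st2$m),
               herbscreen:::flatten_params(ref$state$m), tolerance = 1e-13)
  expect_equal(herbscreen:::flatten_params(st2$v),
               herbscreen:::flatten_params(ref$state$v), tolerance = 1e-13)
})

make_train_sim <- function(seed = 1L) {
  spec <- synthetic_spec(n_records = 90L, vocab_size = 12L, core_herbs = 4:6,
                         core_effect = 3, core_rate = 0.4, intercept = -1,
                         formula_size_range = c(2L, 6L), block_size = 2L,
                         label_noise = 0, seed = seed)
  generate_cohort(spec)
}

test_that("training runs, reproduces, and leaves the input model untouched", {
  sim <- make_train_sim()
  cfg <- ndcnn_config(input_dim = 12L, branch_kernel_sizes = c(1L, 3L),
                      branch_filters = 4L, second_filters = 4L,
                      fc_sizes = c(16L, 8L), epochs = 3L, seed = 2L)
  m0 <- ndcnn_init(cfg)
  before <- herbscreen:::flatten_params(m0$params)
  tr1 <- ndcnn_train(m0, sim$cohort, sim$cohort)
  tr2 <- ndcnn_train(m0, sim$cohort, sim$cohort)
  expect_identical(before, herbscreen:::flatten_params(m0$params))
  expect_identical(tr1$history, tr2$history)
  expect_identical(herbscreen:::flatten_params(tr1$model$params),
                   herbscreen:::flatten_params(tr2$model$params))
  h <- tr1$history
  expect_identical(nrow(h), 3L)
  expect_identical(h$epoch, 1:3)
  expect_true(all(h$train_acc >= 0 & h$train_acc <= 1))
  expect_true(all(h$test_acc >= 0 & h$test_acc <= 1))
  expect_true(all(h$train_loss >= 0) && all(h$test_loss >= 0))
  expect_true(all(is.finite(herbscreen:::flatten_params(tr1$model$params))))
})

test_that("ndcnn_evaluate agrees with a direct whole-cohort computation", {
  sim <- make_train_sim(seed = 3L)
  model <- make_tiny_model(seed = 6L)
  ev <- ndcnn_evaluate(model, sim$cohort, chunk_size = 17L)
  probs <- ndcnn_forward(model, sim$cohort$matrix)
  pred <- as.integer(probs[, 2L] > probs[, 1L])
  expect_equal(ev$accuracy, mean(pred == sim$cohort$labels), tolerance = 1e-12)
  expect_equal(ev$loss,
               cross_entropy(probs, herbscreen:::one_hot(sim$cohort$labels)),
               tolerance = 1e-12)
})

test_that("argmax ties break toward ineffective", {
  model <- make_tiny_model(seed = 1L)
  # zero all parameters: softmax is uniform, a tie at every row
  model$params <- herbscreen:::param_map(function(x) x * 0, model$params)
  cohort <- herbscreen:::encoded_cohort(
    matrix(c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L), 1L, 12L),
    labels = 0L, case_ids = "t1")
  ev <- ndcnn_evaluate(model, cohort)
  expect_identical(ev$accuracy, 1)  # tie predicted as class 0 = ineffective
})

test_that("predict_effective_prob returns the effective-class column", {
  model <- make_tiny_model(seed = 9L)
  set.seed(1)
  X <- matrix(rbinom(24L, 1L, 0.5), 2L, 12L)
  expect_identical(predict_effective_prob(model, X),
                   unname(ndcnn_forward(model, X)[, 2L]))
})

test_that("history CSV round-trips with provenance comments", {
  h <- data.frame(epoch = 1:2, train_loss = c(0.5, 0.4),
                  test_loss = c(0.6, 0.55), train_acc = c(0.7, 0.8),
                  test_acc = c(0.65, 0.7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(h, path, header_lines = "# config_hash: abc")
  expect_identical(readLines(path)[1L], "# config_hash: abc")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back, h)
})

test_that("checkpoints round-trip parameters bitwise", {
  model <- make_tiny_model(seed = 14L)
  vocab <- herb_vocabulary(sprintf("h%02d", 1:12))
  path <- withr::local_tempfile(fileext = ".json")
  save_ndcnn(model, path, vocab)
  back <- load_ndcnn(path)
  expect_identical(herbscreen:::flatten_params(back$model$params),
                   herbscreen:::flatten_params(model$params))
  expect_identical(unclass(back$vocab), unclass(vocab))
  expect_identical(unclass(back$model$config), unclass(model$config))
  expect_error(load_ndcnn(withr::local_tempfile()), "not found")
})
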