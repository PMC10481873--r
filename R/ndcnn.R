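# Multi-scale one-dimensional convolutional efficacy classifier ("NDCNN").
#
# Architecture: the binary bag-of-words prescription vector (length n, single
# channel) is fed to parallel 1-D convolution branches with odd kernel sizes
# (default 1/3/5, 128 filters each, stride 1, zero "same" padding, ReLU).
# Branch feature maps are concatenated along the channel axis into an
# n x (branches * filters) map, convolved once more (kernel 3, 128 filters,
# ReLU), flattened across positions (default; global max pooling over
# positions is the configurable alternative), and passed through fully
# connected ReLU layers (default 1024, 512) to a 2-unit softmax over
# {ineffective, effective}.
#
# Pooling note: the convolution weights are shared across positions, so after
# GLOBAL MAX pooling the network is position-invariant — it can detect local
# presence motifs anywhere in the vocabulary but cannot tell which herb
# produced them, and therefore cannot represent herb-identity-dependent
# efficacy. Flattening preserves position and is the default.
#
# Class convention (fixed throughout the package): class index 1 =
# "ineffective" (label 0), class index 2 = "effective" (label 1). Argmax ties
# are broken toward the lower class index, i.e. toward "ineffective".
#
# Implementation: convolutions are lowered to dense GEMM via im2col, so all
# heavy arithmetic runs in BLAS. Gradients are derived by hand and verified
# against central finite differences in the test suite; optimisation is Adam.

CLASS_NAMES <- c("ineffective", "effective")

#' Classifier configuration
#'
#' Defaults follow the published architecture: kernels 1/3/5 with 128 filters
#' per branch, a second kernel-3 convolution with 128 filters, fully connected
#' layers of 1024 and 512 units, a 2-unit softmax output, 25 training epochs
#' and the Adam optimizer. Batch size (32), learning rate (1e-3) and the
#' flatten reduction before the fully connected stack are implementation
#' defaults documented in the package vignette.
#'
#' @param input_dim Length of the input vector = vocabulary size (default 334).
#' @param branch_kernel_sizes Odd kernel sizes of the parallel first-layer
#'   branches (default `c(1, 3, 5)`).
#' @param branch_filters Filters per branch (default 128).
#' @param second_kernel_size Kernel size of the convolution applied to the
#'   concatenated feature map (default 3, odd).
#' @param second_filters Filters of the second convolution (default 128).
#' @param fc_sizes Sizes of the hidden fully connected layers
#'   (default `c(1024, 512)`).
#' @param output_size Number of output classes; must be 2.
#' @param epochs Training epochs (default 25).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed controlling initialisation and batch shuffling.
#' @param pooling_mode `"flatten"` (default) concatenates the final feature
#'   map across positions, preserving which herb produced which activation;
#'   `"global_max"` pools over positions instead. Because the convolution
#'   weights are shared across positions, global max pooling makes the
#'   network position-invariant: it can detect local presence motifs anywhere
#'   in the vocabulary but cannot tell herbs apart, so it cannot learn
#'   herb-identity-dependent efficacy (see the vignette).
#' @return An `ndcnn_config` list.
#' @export
ndcnn_config <- function(input_dim = 334L,
                         branch_kernel_sizes = c(1L, 3L, 5L),
                         branch_filters = 128L,
                         second_kernel_size = 3L,
                         second_filters = 128L,
                         fc_sizes = c(1024L, 512L),
                         output_size = 2L,
                         epochs = 25L,
                         learning_rate = 1e-3,
                         batch_size = 32L,
                         seed = 1L,
                         pooling_mode = c("flatten", "global_max")) {
  pooling_mode <- match.arg(pooling_mode)
  cfg <- list(input_dim = as.integer(input_dim),
              branch_kernel_sizes = as.integer(branch_kernel_sizes),
              branch_filters = as.integer(branch_filters),
              second_kernel_size = as.integer(second_kernel_size),
              second_filters = as.integer(second_filters),
              fc_sizes = as.integer(fc_sizes),
              output_size = as.integer(output_size),
              epochs = as.integer(epochs),
              learning_rate = as.numeric(learning_rate),
              batch_size = as.integer(batch_size),
              seed = as.integer(seed),
              pooling_mode = pooling_mode)
  validate_ndcnn_config(cfg)
  structure(cfg, class = "ndcnn_config")
}

validate_ndcnn_config <- function(cfg) {
  ks <- c(cfg$branch_kernel_sizes, cfg$second_kernel_size)
  if (any(ks < 1L) || any(ks %% 2L == 0L)) {
    stopf("kernel sizes must be odd and >= 1, got: %s", paste(ks, collapse = ", "))
  }
  counts <- c(cfg$input_dim, cfg$branch_filters, cfg$second_filters,
              cfg$fc_sizes, cfg$epochs, cfg$batch_size)
  if (any(counts < 1L)) stopf("all size/count parameters must be positive")
  if (cfg$output_size != 2L) {
    stopf("output_size must be 2 (ineffective/effective), got %d", cfg$output_size)
  }
  if (cfg$learning_rate <= 0) stopf("learning_rate must be positive")
  invisible(cfg)
}

# Input dimension of the first fully connected layer.
fc_input_dim <- function(cfg) {
  if (cfg$pooling_mode == "global_max") cfg$second_filters
  else cfg$input_dim * cfg$second_filters
}

#' Initialise a classifier
#'
#' Weights are drawn from a uniform He-style fan-in distribution
#' `U(-sqrt(6 / fan_in), sqrt(6 / fan_in))`; biases start at zero. The draw is
#' fully determined by `seed` (identical seeds give bitwise-identical
#' parameters).
#'
#' @param config An [ndcnn_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An `ndcnn_model`: list with elements `config` and `params`.
#' @export
ndcnn_init <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ndcnn_config"))
  he_unif <- function(nr, nc, fan_in) {
    lim <- sqrt(6 / fan_in)
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- with_seed(derive_seed(seed, 0L), {
    p <- list()
    p$branches <- lapply(config$branch_kernel_sizes, function(k) {
      list(W = he_unif(k, config$branch_filters, k),
           b = numeric(config$branch_filters))
    })
    c_in <- length(config$branch_kernel_sizes) * config$branch_filters
    p$conv2 <- list(
      W = he_unif(config$second_kernel_size * c_in, config$second_filters,
                  config$second_kernel_size * c_in),
      b = numeric(config$second_filters))
    dims <- c(fc_input_dim(config), config$fc_sizes, config$output_size)
    p$fc <- lapply(seq_len(length(dims) - 1L), function(i) {
      list(W = he_unif(dims[i], dims[i + 1L], dims[i]),
           b = numeric(dims[i + 1L]))
    })
    p
  })
  structure(list(config = config, params = params), class = "ndcnn_model")
}

#' @export
print.ndcnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ndcnn_model> input %d | branches k=%s x %d filters | conv k=%d x %d | fc %s | softmax %d\n",
    cfg$input_dim, paste(cfg$branch_kernel_sizes, collapse = "/"),
    cfg$branch_filters, cfg$second_kernel_size, cfg$second_filters,
    paste(cfg$fc_sizes, collapse = "-"), cfg$output_size))
  cat(sprintf("  %d parameters, pooling = %s\n",
              n_params(x$params), cfg$pooling_mode))
  invisible(x)
}

n_params <- function(p) {
  sum(unlist(rapply(p, length, how = "list")))
}

# ---- forward pass ----------------------------------------------------------
#
# Feature maps are (B*n) x C matrices with position fastest within sample
# (row = (b-1)*n + pos). Convolutions are lowered to GEMM: cpp_im2col gathers
# the k shifted copies (zero "same" padding), the product with the (k*C) x F
# weight matrix is the convolution, and cpp_col2im is the adjoint gather used
# in backpropagation.

row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass. X: B x input_dim numeric/integer matrix. Returns class
# probabilities (B x 2) and, if keep_cache, the intermediates needed for
# backpropagation. ws is an optional training workspace (see train_workspace);
# when supplied and sized for this batch, the large im2col gather is written
# into its reusable buffer instead of a fresh allocation.
nd_forward <- function(model, X, keep_cache = FALSE, ws = NULL) {
  cfg <- model$config
  p <- model$params
  n <- cfg$input_dim
  B <- nrow(X)
  if (ncol(X) != n) {
    stopf("input has %d columns but the model expects %d", ncol(X), n)
  }
  Fb <- cfg$branch_filters
  xmat <- matrix(as.vector(t(X)), ncol = 1L)  # (B*n) x 1, position fastest

  nb <- length(cfg$branch_kernel_sizes)
  use_ws <- !is.null(ws) && ws$B == B
  xcols <- vector("list", nb)
  if (use_ws) {
    # workspace buffers are overwritten on every call; everything cached from
    # them is consumed within the same batch (see nd_backward)
    A <- ws$a
    for (i in seq_len(nb)) {
      k <- cfg$branch_kernel_sizes[i]
      cpp_im2col_into(xmat, k, n, B, ws$xc[[i]])
      cpp_gemm_bias_relu_into_cols(ws$xc[[i]], p$branches[[i]]$W,
                                   p$branches[[i]]$b, TRUE, A, (i - 1L) * Fb)
      if (keep_cache) xcols[[i]] <- ws$xc[[i]]
    }
    cpp_im2col_into(A, cfg$second_kernel_size, n, B, ws$acols)
    Acols <- ws$acols
    A2 <- ws$a2
    cpp_gemm_bias_relu_into_cols(Acols, p$conv2$W, p$conv2$b, TRUE, A2, 0L)
  } else {
    A <- matrix(0, n * B, nb * Fb)
    for (i in seq_len(nb)) {
      k <- cfg$branch_kernel_sizes[i]
      Xc <- cpp_im2col(xmat, k, n, B)
      Z <- Xc %*% p$branches[[i]]$W
      cpp_add_bias_relu(Z, p$branches[[i]]$b, TRUE)
      A[, (i - 1L) * Fb + seq_len(Fb)] <- Z
      if (keep_cache) xcols[[i]] <- Xc
    }
    Acols <- cpp_im2col(A, cfg$second_kernel_size, n, B)
    A2 <- Acols %*% p$conv2$W
    cpp_add_bias_relu(A2, p$conv2$b, TRUE)
  }

  if (cfg$pooling_mode == "global_max") {
    F2 <- cfg$second_filters
    pool <- cpp_pool_max(A2, n, B)
    P <- pool$P
    pool_idx <- pool$idx                  # B x F2, 1-based argmax positions
  } else {
    arr <- array(A2, c(n, B, cfg$second_filters))
    P <- matrix(aperm(arr, c(2L, 1L, 3L)), B, n * cfg$second_filters)
    pool_idx <- NULL
  }

  hs <- vector("list", length(p$fc) + 1L)
  hs[[1L]] <- P
  for (i in seq_along(p$fc)) {
    Z <- hs[[i]] %*% p$fc[[i]]$W
    cpp_add_bias_relu(Z, p$fc[[i]]$b, i < length(p$fc))
    hs[[i + 1L]] <- Z
  }
  probs <- row_softmax(hs[[length(hs)]])
  colnames(probs) <- CLASS_NAMES

  cache <- NULL
  if (keep_cache) {
    cache <- list(xcols = xcols, A = A, Acols = Acols, mask2 = A2 > 0,
                  pool_idx = pool_idx, hs = hs, B = B)
  }
  list(probs = probs, cache = cache)
}

#' Forward pass: class probabilities for a batch
#'
#' Each row of `batch` is treated as a length-`input_dim`, single-channel
#' sequence. Returns the per-row softmax probabilities of the two classes.
#'
#' @param model An [ndcnn_init()]-style `ndcnn_model`.
#' @param batch Matrix (rows = cases) or single vector of length `input_dim`.
#'   The model is defined on binary bag-of-words input; non-binary values are
#'   accepted with a warning.
#' @return Numeric matrix (rows x 2) with columns `ineffective`, `effective`;
#'   rows sum to 1.
#' @export
ndcnn_forward <- function(model, batch) {
  stopifnot(inherits(model, "ndcnn_model"))
  if (is.null(dim(batch))) batch <- matrix(batch, nrow = 1L)
  batch <- as.matrix(batch)
  storage.mode(batch) <- "double"
  if (!all(batch %in% c(0, 1))) {
    warning("input is not binary 0/1; the classifier is defined on ",
            "bag-of-words prescriptions", call. = FALSE)
  }
  nd_forward(model, batch)$probs
}

#' Mean cross-entropy loss
#'
#' `-mean_i sum_h targets[i,h] * log(predictions[i,h])` with probabilities
#' clipped to `[eps, 1 - eps]`, `eps = 1e-12`. For the 2-unit softmax output
#' this categorical form coincides with binary cross-entropy.
#'
#' @param predictions Probability matrix (rows sum to 1).
#' @param targets One-hot matrix of the same shape.
#' @param eps Clipping bound (default 1e-12).
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(predictions, targets, eps = 1e-12) {
  predictions <- as.matrix(predictions)
  targets <- as.matrix(targets)
  if (!all(dim(predictions) == dim(targets))) {
    stopf("predictions are %dx%d but targets are %dx%d",
          nrow(predictions), ncol(predictions), nrow(targets), ncol(targets))
  }
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(rowSums(targets * log(p)))
}

one_hot <- function(labels, k = 2L) {
  m <- matrix(0, length(labels), k)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

# ---- backward pass ---------------------------------------------------------

# Mean-cross-entropy gradients for one batch. Returns list(loss, grads) with
# grads mirroring model$params. Also returns probs for metric bookkeeping.
# ws: optional training workspace (see train_workspace) of preallocated
# buffers for the large intermediates; when supplied and sized for this batch,
# the returned g$fc[[i]]$W alias its buffers, so callers must consume the
# gradients before the next nd_backward call overwrites them. ndcnn_train does
# this to avoid reallocating hundreds of MB per mini-batch.
nd_backward <- function(model, X, targets, ws = NULL) {
  cfg <- model$config
  p <- model$params
  n <- cfg$input_dim
  if (!is.null(ws) && (ws$B != nrow(X) || is.null(ws$fc_w))) {
    ws <- NULL  # ragged final batch, or a forward-only workspace
  }
  fw <- nd_forward(model, X, keep_cache = TRUE, ws = ws)
  cache <- fw$cache
  B <- cache$B
  probs <- fw$probs
  loss <- cross_entropy(probs, targets)

  g <- list(branches = vector("list", length(p$branches)),
            conv2 = NULL, fc = vector("list", length(p$fc)))

  # fully connected stack
  dZ <- (probs - targets) / B
  for (i in rev(seq_along(p$fc))) {
    H_in <- cache$hs[[i]]
    if (is.null(ws)) {
      gW <- crossprod(H_in, dZ)
    } else {
      cpp_crossprod_into(H_in, dZ, ws$fc_w[[i]])
      gW <- ws$fc_w[[i]]
    }
    g$fc[[i]] <- list(W = gW, b = colSums(dZ))
    if (i > 1L) {
      dH <- tcrossprod(dZ, p$fc[[i]]$W)
      dZ <- dH * (H_in > 0)
    } else if (is.null(ws)) {
      dP <- tcrossprod(dZ, p$fc[[i]]$W)
    } else {
      cpp_tcrossprod_into(dZ, p$fc[[i]]$W, ws$dp)
      dP <- ws$dp
    }
  }

  # un-pool into the final feature map
  F2 <- cfg$second_filters
  if (cfg$pooling_mode == "global_max") {
    dA2 <- matrix(0, n * B, F2)
    j <- seq_len(B * F2)                  # column order: b fastest within f
    b <- ((j - 1L) %% B) + 1L
    f <- ((j - 1L) %/% B) + 1L
    lin <- (f - 1L) * (n * B) + (b - 1L) * n + cache$pool_idx
    dA2[lin] <- dP                        # dP is B x F2, b fastest: matches j
  } else {
    arr <- array(dP, c(B, n, F2))
    dA2 <- matrix(aperm(arr, c(2L, 1L, 3L)), n * B, F2)
  }

  dZ2 <- dA2 * cache$mask2
  g$conv2 <- list(W = crossprod(cache$Acols, dZ2), b = colSums(dZ2))
  if (is.null(ws)) {
    dAcols <- tcrossprod(dZ2, p$conv2$W)
  } else {
    cpp_tcrossprod_into(dZ2, p$conv2$W, ws$dacols)
    dAcols <- ws$dacols
  }

  # col2im: scatter-add taps back onto the concatenated branch map
  C <- ncol(cache$A)
  dA <- cpp_col2im(dAcols, cfg$second_kernel_size, n, B, C)

  Fb <- cfg$branch_filters
  for (i in seq_along(p$branches)) {
    cols <- (i - 1L) * Fb + seq_len(Fb)
    dZk <- dA[, cols, drop = FALSE] * (cache$A[, cols, drop = FALSE] > 0)
    g$branches[[i]] <- list(W = crossprod(cache$xcols[[i]], dZk),
                            b = colSums(dZk))
  }

  list(loss = loss, grads = g, probs = probs)
}

# ---- parameter utilities / Adam -------------------------------------------

# Apply f elementwise over two parameter trees of identical shape.
param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(param_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

param_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, param_map, f = f)
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

relist_params <- function(v, skeleton) {
  i <- 0L
  param_map(function(x) {
    out <- v[i + seq_along(x)]
    i <<- i + length(x)
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }, skeleton)
}

adam_init <- function(params) {
  list(m = param_map(function(x) x * 0, params),
       v = param_map(function(x) x * 0, params),
       t = 0L)
}

# Reusable buffers for the large per-batch intermediates (im2col gathers and
# the wide gradient GEMM outputs), sized for a full mini-batch of B rows.
# Reallocating these fresh on every batch dominated full-scale training time.
train_workspace <- function(cfg, params, B, backward = TRUE) {
  n <- cfg$input_dim
  c_in <- length(cfg$branch_kernel_sizes) * cfg$branch_filters
  cols <- cfg$second_kernel_size * c_in
  ws <- list(B = as.integer(B),
             xc = lapply(cfg$branch_kernel_sizes,
                         function(k) matrix(0, n * B, k)),
             a = matrix(0, n * B, c_in),
             a2 = matrix(0, n * B, cfg$second_filters),
             acols = matrix(0, n * B, cols))
  if (backward) {
    ws$dacols <- matrix(0, n * B, cols)
    ws$dp <- matrix(0, B, fc_input_dim(cfg))
    ws$fc_w <- lapply(params$fc, function(l) matrix(0, nrow(l$W), ncol(l$W)))
  }
  ws
}

# Reference (pure R) Adam step; the training loop uses the in-place variant
# below, whose equivalence to this one is checked in the test suite.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- param_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                    state$m, state$v)
  params <- param_map2(`-`, params, upd)
  list(params = params, state = state)
}

# In-place Adam step: mutates the params / m / v leaves through an Rcpp kernel
# instead of rebuilding four full-size parameter trees per mini-batch, which
# dominated the training wall time at full scale via allocation and GC. The
# caller must own private copies of all three trees (ndcnn_train deep-copies
# params up front; adam_init builds m and v fresh).
adam_update_inplace <- function(params, grads, m, v, lr, t,
                                beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.list(params)) {
    for (i in seq_along(params)) {
      adam_update_inplace(params[[i]], grads[[i]], m[[i]], v[[i]],
                          lr, t, beta1, beta2, eps)
    }
  } else {
    cpp_adam_update(params, m, v, grads, lr, beta1, beta2, eps, t)
  }
  invisible(NULL)
}

# ---- training / evaluation -------------------------------------------------

#' Evaluate a classifier on a cohort
#'
#' Accuracy is the fraction of rows whose argmax class equals the label, ties
#' broken toward "ineffective" (the lower class index); loss is mean
#' cross-entropy.
#'
#' @param model An `ndcnn_model`.
#' @param cohort An [encoded_cohort()].
#' @param chunk_size Rows per forward-pass chunk (memory control).
#' @return List with elements `loss` and `accuracy`.
#' @export
ndcnn_evaluate <- function(model, cohort, chunk_size = 128L) {
  stopifnot(inherits(model, "ndcnn_model"), inherits(cohort, "encoded_cohort"))
  n <- nrow(cohort$matrix)
  if (n == 0L) stopf("cannot evaluate on an empty cohort")
  ws <- train_workspace(model$config, model$params, min(chunk_size, n),
                        backward = FALSE)
  loss_sum <- 0
  correct <- 0L
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    X <- cohort$matrix[idx, , drop = FALSE]
    storage.mode(X) <- "double"
    probs <- nd_forward(model, X, ws = ws)$probs
    t_oh <- one_hot(cohort$labels[idx])
    loss_sum <- loss_sum + cross_entropy(probs, t_oh) * length(idx)
    pred <- as.integer(probs[, 2L] > probs[, 1L])  # tie -> ineffective
    correct <- correct + sum(pred == cohort$labels[idx])
  }
  list(loss = loss_sum / n, accuracy = correct / n)
}

#' Train the classifier
#'
#' Mini-batch gradient descent with the Adam optimizer on mean cross-entropy,
#' for `model$config$epochs` epochs. Per-epoch training loss/accuracy are the
#' running means over the epoch's mini-batches (computed before each update);
#' test metrics are evaluated on `test_set` after each epoch. Batch order is
#' reshuffled every epoch from the model seed, so identical seeds and data
#' reproduce the history exactly.
#'
#' @param model An initialised `ndcnn_model`.
#' @param train_set,test_set [encoded_cohort()]s encoded against the same
#'   vocabulary.
#' @param verbose Print per-epoch metrics (default FALSE).
#' @return List with elements `model` (trained) and `history` (data frame with
#'   columns `epoch`, `train_loss`, `test_loss`, `train_acc`, `test_acc`; one
#'   row per epoch).
#' @export
ndcnn_train <- function(model, train_set, test_set, verbose = FALSE) {
  stopifnot(inherits(model, "ndcnn_model"),
            inherits(train_set, "encoded_cohort"),
            inherits(test_set, "encoded_cohort"))
  cfg <- model$config
  n <- nrow(train_set$matrix)
  if (n == 0L) stopf("training set is empty")
  if (ncol(train_set$matrix) != cfg$input_dim ||
      ncol(test_set$matrix) != cfg$input_dim) {
    stopf("cohorts must be encoded against a %d-herb vocabulary", cfg$input_dim)
  }
  X_all <- train_set$matrix
  storage.mode(X_all) <- "double"
  y_all <- train_set$labels

  # Private deep copy of the parameters: the Adam update below mutates the
  # leaves in place, and the caller's model must stay untouched.
  model$params <- param_map(function(x) x + 0, model$params)
  state <- adam_init(model$params)
  ws <- train_workspace(cfg, model$params, min(cfg$batch_size, n))
  tstep <- 0L
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     test_loss = NA_real_, train_acc = NA_real_,
                     test_acc = NA_real_)
  with_seed(derive_seed(cfg$seed, 1L), {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      loss_sum <- 0
      correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        X <- X_all[idx, , drop = FALSE]
        t_oh <- one_hot(y_all[idx])
        bk <- nd_backward(model, X, t_oh, ws = ws)
        loss_sum <- loss_sum + bk$loss * length(idx)
        pred <- as.integer(bk$probs[, 2L] > bk$probs[, 1L])
        correct <- correct + sum(pred == y_all[idx])
        tstep <- tstep + 1L
        adam_update_inplace(model$params, bk$grads, state$m, state$v,
                            cfg$learning_rate, tstep)
      }
      ev <- ndcnn_evaluate(model, test_set)
      hist$train_loss[ep] <- loss_sum / n
      hist$train_acc[ep] <- correct / n
      hist$test_loss[ep] <- ev$loss
      hist$test_acc[ep] <- ev$accuracy
      if (verbose) {
        message(sprintf(
          "epoch %2d/%d  train loss %.4f acc %.3f | test loss %.4f acc %.3f",
          ep, cfg$epochs, hist$train_loss[ep], hist$train_acc[ep],
          hist$test_loss[ep], hist$test_acc[ep]))
      }
    }
  })
  list(model = model, history = hist)
}

#' Predicted probability that a combination is effective
#'
#' @param model An `ndcnn_model`.
#' @param combination Binary vector of length `input_dim`, or a matrix of such
#'   rows.
#' @return Numeric vector of `P(effective)` values in `[0, 1]`.
#' @export
predict_effective_prob <- function(model, combination) {
  probs <- ndcnn_forward(model, combination)
  unname(probs[, 2L])
}

#' Export a training history as CSV
#'
#' Columns `epoch`, `train_loss`, `test_loss`, `train_acc`, `test_acc` — the
#' data behind loss/accuracy training curves.
#'
#' @param history History data frame from [ndcnn_train()].
#' @param path File path.
#' @param header_lines Optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path, header_lines = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.csv(history, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
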