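# Independent straight-line reference implementations used as oracles.
# Deliberately written with plain loops (no im2col, no GEMM lowering, no
# shared code with the package internals) so that agreement is evidence of
# correctness rather than of shared bugs.

# 1-D "same" zero-padded convolution of a (n x C) map with a ((k*C) x F)
# weight matrix; returns n x F. Weight row (t-1)*C + c is the tap for channel
# c at offset t - 1 - (k-1)/2.
ref_conv1d <- function(map, W, b, k) {
  n <- nrow(map)
  C <- ncol(map)
  F <- ncol(W)
  half <- (k - 1L) %/% 2L
  out <- matrix(0, n, F)
  for (f in seq_len(F)) {
    for (pos in seq_len(n)) {
      acc <- b[f]
      for (t in seq_len(k)) {
        src <- pos + (t - 1L) - half
        if (src >= 1L && src <= n) {
          for (c in seq_len(C)) {
            acc <- acc + map[src, c] * W[(t - 1L) * C + c, f]
          }
        }
      }
      out[pos, f] <- acc
    }
  }
  out
}

ref_relu <- function(x) pmax(x, 0)

ref_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Full reference forward pass for ONE input vector; returns the 2-class
# probability vector.
ref_forward_one <- function(model, x) {
  cfg <- model$config
  p <- model$params
  xmap <- matrix(as.numeric(x), ncol = 1L)
  branch_maps <- lapply(seq_along(cfg$branch_kernel_sizes), function(i) {
    k <- cfg$branch_kernel_sizes[i]
    ref_relu(ref_conv1d(xmap, p$branches[[i]]$W, p$branches[[i]]$b, k))
  })
  A <- do.call(cbind, branch_maps)
  A2 <- ref_relu(ref_conv1d(A, p$conv2$W, p$conv2$b, cfg$second_kernel_size))
  h <- if (cfg$pooling_mode == "global_max") {
    apply(A2, 2L, max)
  } else {
    # flatten layout: position fastest within filter, i.e. entry
    # (f-1)*n + pos = A2[pos, f]
    as.numeric(A2)
  }
  for (i in seq_along(p$fc)) {
    h <- as.numeric(h %*% p$fc[[i]]$W) + p$fc[[i]]$b
    if (i < length(p$fc)) h <- ref_relu(h)
  }
  ref_softmax(h)
}

# Central finite-difference gradient of the mean cross-entropy for one batch,
# flattened over all parameters.
ref_fd_gradient <- function(model, X, targets, h = 1e-5) {
  flat <- herbscreen:::flatten_params(model$params)
  loss_at <- function(v) {
    m <- model
    m$params <- herbscreen:::relist_params(v, model$params)
    cross_entropy(herbscreen:::nd_forward(m, X)$probs, targets)
  }
  g <- numeric(length(flat))
  for (j in seq_along(flat)) {
    up <- flat; up[j] <- up[j] + h
    dn <- flat; dn[j] <- dn[j] - h
    g[j] <- (loss_at(up) - loss_at(dn)) / (2 * h)
  }
  g
}

# Small deterministic cohort for encoder-level tests.
make_tiny_records <- function() {
  prescription_records(
    case_id = c("c1", "c2", "c3", "c4"),
    herbs = list(c("ginseng", "licorice"),
                 c("licorice", "astragalus", "angelica"),
                 c("ginseng"),
                 c("angelica", "ginseng", "licorice")),
    outcome = c("complete_remission", "progressive", "stable",
                "partial_remission"))
}

# Small trained-free model: deterministic params for a tiny config.
make_tiny_model <- function(input_dim = 12L, seed = 7L,
                            pooling_mode = "flatten") {
  cfg <- ndcnn_config(input_dim = input_dim, branch_kernel_sizes = c(1L, 3L),
                      branch_filters = 3L, second_kernel_size = 3L,
                      second_filters = 4L, fc_sizes = c(6L, 5L),
                      epochs = 2L, seed = seed, pooling_mode = pooling_mode)
  ndcnn_init(cfg)
}
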