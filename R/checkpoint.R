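# Portable model checkpoints: a single JSON file holding the configuration as
# structured text plus every parameter array as little-endian IEEE-754 doubles
# in base64, so that a round trip reproduces parameters bitwise on any
# platform. The vocabulary the model was trained against travels with the
# checkpoint so that search-time encodings cannot silently drift.

CHECKPOINT_FORMAT <- "herbscreen-ndcnn"
CHECKPOINT_VERSION <- 1L

encode_array <- function(x) {
  list(dim = if (is.matrix(x)) dim(x) else length(x),
       data = jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                            size = 8L, endian = "little")))
}

decode_array <- function(a) {
  raw <- jsonlite::base64_dec(a$data)
  v <- readBin(raw, "double", n = length(raw) %/% 8L, size = 8L,
               endian = "little")
  d <- as.integer(unlist(a$dim))
  if (prod(d) != length(v)) stopf("corrupt checkpoint: array size mismatch")
  if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v
}

param_tree_encode <- function(p) {
  if (is.list(p) && !all(c("dim", "data") %in% names(p))) {
    lapply(p, param_tree_encode)
  } else {
    encode_array(p)
  }
}

param_tree_decode <- function(p) {
  if (is.list(p) && !all(c("dim", "data") %in% names(p))) {
    lapply(p, param_tree_decode)
  } else {
    decode_array(p)
  }
}

#' Save / load a classifier checkpoint
#'
#' @param model An `ndcnn_model`.
#' @param path File path (JSON).
#' @param vocab Optional [herb_vocabulary()] stored alongside the model.
#' @return `path`, invisibly (save); a list with elements `model` and `vocab`
#'   (`NULL` if none was stored) (load).
#' @export
save_ndcnn <- function(model, path, vocab = NULL) {
  stopifnot(inherits(model, "ndcnn_model"))
  obj <- list(format = CHECKPOINT_FORMAT,
              version = CHECKPOINT_VERSION,
              config = unclass(model$config),
              vocabulary = if (!is.null(vocab)) as.character(vocab),
              params = param_tree_encode(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ndcnn
#' @export
load_ndcnn <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, CHECKPOINT_FORMAT)) {
    stopf("not a %s checkpoint: %s", CHECKPOINT_FORMAT, path)
  }
  if (!identical(as.integer(obj$version), CHECKPOINT_VERSION)) {
    stopf("unsupported checkpoint version %s (supported: %d)",
          obj$version, CHECKPOINT_VERSION)
  }
  cfgl <- obj$config
  cfg <- ndcnn_config(input_dim = cfgl$input_dim,
                      branch_kernel_sizes = unlist(cfgl$branch_kernel_sizes),
                      branch_filters = cfgl$branch_filters,
                      second_kernel_size = cfgl$second_kernel_size,
                      second_filters = cfgl$second_filters,
                      fc_sizes = unlist(cfgl$fc_sizes),
                      output_size = cfgl$output_size,
                      epochs = cfgl$epochs,
                      learning_rate = cfgl$learning_rate,
                      batch_size = cfgl$batch_size,
                      seed = cfgl$seed,
                      pooling_mode = cfgl$pooling_mode)
  params <- param_tree_decode(obj$params)
  model <- structure(list(config = cfg, params = params), class = "ndcnn_model")
  check_param_shapes(model)
  vocab <- if (!is.null(obj$vocabulary)) {
    v <- herb_vocabulary(unlist(obj$vocabulary))
    if (length(v) != cfg$input_dim) {
      stopf("checkpoint vocabulary has %d herbs but config input_dim is %d",
            length(v), cfg$input_dim)
    }
    v
  }
  list(model = model, vocab = vocab)
}

# Validate stored parameter shapes against the stored config.
check_param_shapes <- function(model) {
  cfg <- model$config
  p <- model$params
  ref <- ndcnn_init(cfg, seed = 1L)$params
  ok <- tryCatch({
    same <- function(a, b) identical(dim(a) %||% length(a),
                                     dim(b) %||% length(b))
    all(unlist(param_map2(same, p, ref)))
  }, error = function(e) FALSE)
  if (!isTRUE(ok)) {
    stopf("checkpoint parameter shapes do not match its configuration")
  }
  if (!all(is.finite(flatten_params(p)))) {
    stopf("checkpoint contains non-finite parameters")
  }
  invisible(model)
}
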