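# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically maps a master seed and an offset to a new seed in
#' `[1, 2^31 - 2]`, so that independent stages (initialisation, shuffling,
#' cohort generation, search) consume distinct but reproducible streams.
#'
#' @param seed Integer master seed.
#' @param offset Integer stage offset.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1000003 * (as.double(offset) + 1)
  as.integer(s %% 2147483646) + 1L
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Normalize herb names: exact-string matching after whitespace trimming and
# case folding. Synonym resolution is out of scope (assumed done upstream
# against a pharmacopoeia standard).
normalize_herb_names <- function(x) {
  tolower(trimws(x))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
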