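# Herb vocabulary: the ordered list of standardized herb names that defines
# the positions of the binary bag-of-words encoding. Position is meaningful:
# the classifier's convolutions read local neighbourhoods of the vector, so
# vocabulary order is fixed at construction time and persisted with every
# artifact that depends on it.

#' Construct a herb vocabulary
#'
#' @param names Character vector of unique herb names (already normalized, or
#'   normalized here via whitespace trimming and case folding).
#' @return An object of class `herb_vocabulary`: a character vector of unique
#'   names whose position defines the encoding index.
#' @export
herb_vocabulary <- function(names) {
  names <- normalize_herb_names(as.character(names))
  if (length(names) == 0L) stopf("a vocabulary needs at least one herb name")
  if (anyDuplicated(names)) {
    stopf("duplicate herb names in vocabulary: %s",
          paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  structure(names, class = "herb_vocabulary")
}

#' @export
print.herb_vocabulary <- function(x, ...) {
  cat(sprintf("<herb_vocabulary> %d herbs: %s%s\n", length(x),
              paste(utils::head(unclass(x), 5), collapse = ", "),
              if (length(x) > 5) ", ..." else ""))
  invisible(x)
}

#' Build a vocabulary from prescription records
#'
#' Collects every distinct herb name occurring in any record, in
#' first-occurrence order (record order, then within-record order). The
#' resulting order is the encoding order and should be persisted with
#' [write_vocabulary()] so that downstream runs are reproducible.
#'
#' @param records A prescription data frame as returned by
#'   [read_prescriptions()] (with a list-column `herbs`), or a list of
#'   character vectors of herb names.
#' @return A [herb_vocabulary()].
#' @export
build_vocabulary <- function(records) {
  herbs <- if (is.data.frame(records)) records$herbs else records
  if (length(herbs) == 0L) stopf("cannot build a vocabulary from zero records")
  all_names <- normalize_herb_names(unlist(herbs, use.names = FALSE))
  if (length(all_names) == 0L) stopf("records contain no herb names")
  herb_vocabulary(unique(all_names))
}

#' Encode a prescription as a binary presence/absence vector
#'
#' @param herbs Character vector: the herb names of one prescription.
#' @param vocab A [herb_vocabulary()].
#' @return Integer vector of length `length(vocab)`; entry j is 1 iff herb j
#'   is present.
#' @export
encode_prescription <- function(herbs, vocab) {
  stopifnot(inherits(vocab, "herb_vocabulary"))
  herbs <- normalize_herb_names(herbs)
  idx <- match(unique(herbs), unclass(vocab))
  if (anyNA(idx)) {
    stopf("herb(s) not in vocabulary: %s",
          paste(unique(herbs)[is.na(idx)], collapse = ", "))
  }
  v <- integer(length(vocab))
  v[idx] <- 1L
  v
}

#' Decode a binary vector back to herb names
#'
#' Inverse of [encode_prescription()]: returns the names at the set bits, in
#' vocabulary order.
#'
#' @param genes Binary (0/1) vector of length `length(vocab)`.
#' @param vocab A [herb_vocabulary()].
#' @return Character vector of herb names (possibly empty).
#' @export
decode_prescription <- function(genes, vocab) {
  stopifnot(inherits(vocab, "herb_vocabulary"))
  if (length(genes) != length(vocab)) {
    stopf("vector length %d does not match vocabulary size %d",
          length(genes), length(vocab))
  }
  unclass(vocab)[genes != 0]
}

#' Write / read a vocabulary file
#'
#' TSV with columns `index` (0-based position) and `herb_name`. Lines starting
#' with `#` are treated as comments.
#'
#' @param vocab A [herb_vocabulary()].
#' @param path File path.
#' @param header_lines Optional character vector of `#`-prefixed comment lines
#'   written at the top of the file (e.g. seed / config provenance).
#' @return `path`, invisibly (writer); a [herb_vocabulary()] (reader).
#' @export
write_vocabulary <- function(vocab, path, header_lines = character()) {
  stopifnot(inherits(vocab, "herb_vocabulary"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines("index\therb_name", con)
  writeLines(sprintf("%d\t%s", seq_along(vocab) - 1L, unclass(vocab)), con)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c("integer", "character"))
  if (!all(c("index", "herb_name") %in% names(df))) {
    stopf("vocabulary file %s lacks columns 'index' and 'herb_name'", path)
  }
  herb_vocabulary(df$herb_name[order(df$index)])
}
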