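# Prescription records and their binary encoding.
#
# A prescription record is one treatment protocol: a case id, the set of herbs
# administered, and a 4-level clinical outcome. Outcomes are recoded to a
# binary efficacy label (complete remission / partial remission / stable ->
# effective = 1; progressive -> ineffective = 0) and herb sets are densified
# to rows of a binary matrix over the vocabulary.

#' Four-level treatment outcomes
#'
#' The admissible values of the `outcome` column of a prescriptions file, in
#' decreasing order of response: tumour disappeared, tumour reduced by more
#' than half, roughly unchanged, grew or spread.
#' @export
OUTCOME_LEVELS <- c("complete_remission", "partial_remission", "stable",
                    "progressive")

#' Recode a 4-level outcome to a binary efficacy label
#'
#' Complete remission, partial remission and stable are classified as
#' effective (1); progressive is classified as ineffective (0).
#'
#' @param outcome Character vector of outcomes (elements of [OUTCOME_LEVELS]).
#' @return Integer vector of 0/1 labels (1 = effective).
#' @export
recode_outcome <- function(outcome) {
  outcome <- tolower(trimws(as.character(outcome)))
  bad <- setdiff(unique(outcome), OUTCOME_LEVELS)
  if (length(bad)) {
    stopf("unrecognized outcome value(s): %s (expected one of %s)",
          paste(bad, collapse = ", "), paste(OUTCOME_LEVELS, collapse = ", "))
  }
  as.integer(outcome != "progressive")
}

#' Construct a prescription record table
#'
#' @param case_id Character vector of case identifiers.
#' @param herbs List of character vectors (the herbs of each prescription).
#' @param outcome Character vector of outcomes (see [OUTCOME_LEVELS]).
#' @return A data frame with columns `case_id`, `herbs` (list-column),
#'   `outcome`, of class `prescription_records`.
#' @export
prescription_records <- function(case_id, herbs, outcome) {
  stopifnot(length(case_id) == length(herbs),
            length(case_id) == length(outcome))
  herbs <- lapply(herbs, function(h) {
    h <- normalize_herb_names(as.character(h))
    h <- unique(h[nzchar(h)])
    if (length(h) == 0L) stopf("a prescription must contain at least one herb")
    h
  })
  outcome <- tolower(trimws(as.character(outcome)))
  recode_outcome(outcome)  # validates
  df <- data.frame(case_id = as.character(case_id), stringsAsFactors = FALSE)
  df$herbs <- herbs
  df$outcome <- outcome
  class(df) <- c("prescription_records", "data.frame")
  df
}

#' @export
print.prescription_records <- function(x, ...) {
  cat(sprintf("<prescription_records> %d records, %d distinct herbs\n",
              nrow(x), length(unique(unlist(x$herbs)))))
  tab <- table(factor(x$outcome, levels = OUTCOME_LEVELS))
  print(tab)
  invisible(x)
}

#' Read / write a prescriptions file
#'
#' UTF-8 TSV with a header and columns `case_id`, `herbs` (semicolon-separated
#' herb names) and `outcome` (one of [OUTCOME_LEVELS]). Lines starting with
#' `#` are comments (run provenance such as seed and config hash).
#'
#' @param path File path.
#' @param records A [prescription_records()] table.
#' @param header_lines Optional `#`-prefixed comment lines to write at the top.
#' @return A [prescription_records()] table (reader); `path`, invisibly
#'   (writer).
#' @export
read_prescriptions <- function(path) {
  if (!file.exists(path)) stopf("prescriptions file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("case_id", "herbs", "outcome")
  if (!all(need %in% names(df))) {
    stopf("prescriptions file %s must have columns %s", path,
          paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stopf("prescriptions file %s contains no records", path)
  herbs <- strsplit(df$herbs, ";", fixed = TRUE)
  prescription_records(df$case_id, herbs, df$outcome)
}

#' @rdname read_prescriptions
#' @export
write_prescriptions <- function(records, path, header_lines = character()) {
  stopifnot(inherits(records, "prescription_records"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines("case_id\therbs\toutcome", con)
  writeLines(sprintf("%s\t%s\t%s", records$case_id,
                     vapply(records$herbs, paste, "", collapse = ";"),
                     records$outcome), con)
  invisible(path)
}

#' Encode prescription records against a vocabulary
#'
#' Densifies the herb sets to a binary matrix (records x vocabulary) and
#' recodes the outcomes to binary efficacy labels.
#'
#' @param records A [prescription_records()] table.
#' @param vocab A [herb_vocabulary()]; defaults to the vocabulary built from
#'   `records` in first-occurrence order.
#' @return An object of class `encoded_cohort`: a list with elements `matrix`
#'   (binary integer matrix, columns named by herb), `labels` (integer 0/1,
#'   1 = effective) and `case_ids`.
#' @export
encode_cohort <- function(records, vocab = build_vocabulary(records)) {
  stopifnot(inherits(records, "prescription_records"))
  m <- t(vapply(records$herbs, encode_prescription,
                integer(length(vocab)), vocab = vocab))
  colnames(m) <- unclass(vocab)
  encoded_cohort(m, recode_outcome(records$outcome), records$case_id)
}

#' Construct an encoded cohort from its parts
#'
#' @param matrix Binary (0/1) matrix, one row per case, one column per herb.
#' @param labels Integer 0/1 vector (1 = effective), one per row.
#' @param case_ids Character vector of case identifiers (default `"1"..."n"`).
#' @return An `encoded_cohort` list.
#' @export
encoded_cohort <- function(matrix, labels,
                           case_ids = as.character(seq_len(nrow(matrix)))) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  if (!all(matrix %in% c(0L, 1L))) stopf("cohort matrix must be binary 0/1")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  if (nrow(matrix) != length(labels)) {
    stopf("matrix has %d rows but there are %d labels",
          nrow(matrix), length(labels))
  }
  if (nrow(matrix) != length(case_ids)) {
    stopf("matrix has %d rows but there are %d case ids",
          nrow(matrix), length(case_ids))
  }
  structure(list(matrix = matrix, labels = labels,
                 case_ids = as.character(case_ids)),
            class = "encoded_cohort")
}

#' @export
print.encoded_cohort <- function(x, ...) {
  cat(sprintf(
    "<encoded_cohort> %d cases x %d herbs; %d effective (%.1f%%), %d ineffective\n",
    nrow(x$matrix), ncol(x$matrix), sum(x$labels),
    100 * mean(x$labels), sum(x$labels == 0L)))
  invisible(x)
}

#' Export an encoded cohort as dense CSV
#'
#' One row per case, one column per herb name, plus a final `label` column.
#'
#' @param cohort An [encoded_cohort()].
#' @param path File path.
#' @param header_lines Optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, header_lines = character()) {
  stopifnot(inherits(cohort, "encoded_cohort"))
  df <- as.data.frame(cohort$matrix)
  df$label <- cohort$labels
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.csv(cbind(case_id = cohort$case_ids, df), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Subset an encoded cohort by row index.
cohort_subset <- function(cohort, idx) {
  encoded_cohort(cohort$matrix[idx, , drop = FALSE], cohort$labels[idx],
                 cohort$case_ids[idx])
}

#' Split an encoded cohort into training and test sets
#'
#' The training set receives `floor(train_fraction * n)` records; the
#' remainder goes to the test set. Stratified splitting (the default)
#' preserves the class proportions within one record per class: each class
#' contributes `floor(train_fraction * n_class)` training records and the
#' shortfall against the overall training size is topped up by largest
#' fractional remainder.
#'
#' @param cohort An [encoded_cohort()].
#' @param train_fraction Proportion of records assigned to training
#'   (default 0.8, i.e. the 8:2 split used for model development).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param stratified Preserve class balance across the two sets (default TRUE).
#' @return List with elements `train` and `test` (both [encoded_cohort()]s)
#'   and `train_idx`, `test_idx` (integer row indices into `cohort`).
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed = 1L,
                         stratified = TRUE) {
  stopifnot(inherits(cohort, "encoded_cohort"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must be in (0, 1), got %g", train_fraction)
  }
  n <- nrow(cohort$matrix)
  n_train <- floor(train_fraction * n)
  if (n_train < 1L || n_train >= n) {
    stopf("split would leave an empty set (n = %d, train_fraction = %g)",
          n, train_fraction)
  }
  train_idx <- with_seed(seed, {
    if (stratified) {
      classes <- sort(unique(cohort$labels))
      if (length(classes) < 2L) {
        stopf("stratified split requires both classes in the cohort")
      }
      counts <- vapply(classes, function(cl) sum(cohort$labels == cl), 0L)
      if (any(counts < 2L)) {
        stopf("stratified split requires at least 2 records per class")
      }
      exact <- train_fraction * counts
      take <- floor(exact)
      # top up to the overall floor(train_fraction * n) by largest remainder
      short <- n_train - sum(take)
      if (short > 0L) {
        ord <- order(exact - take, counts, decreasing = TRUE)
        take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1L
      }
      unlist(lapply(seq_along(classes), function(i) {
        rows <- which(cohort$labels == classes[i])
        sample(rows, take[i])
      }))
    } else {
      sample.int(n, n_train)
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = cohort_subset(cohort, train_idx),
       test = cohort_subset(cohort, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}
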