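#' Participants-by-proteins NPX matrix
#'
#' Light container for a participants x proteins matrix of NPX-style (log2
#' relative abundance) values. Missing values are `NA` in `values`; the
#' missingness mask is `is.na(x$values)`.
#'
#' @param values numeric matrix with participant row names and protein column
#'   names.
#' @param protein_ids optional protein identifiers (default: column names).
#' @param panel optional per-protein panel labels, named by protein id.
#' @return An object of class `protein_matrix` with elements `values`,
#'   `protein_ids`, `panel`.
#' @export
protein_matrix <- function(values, protein_ids = colnames(values),
                           panel = NULL) {
  values <- as.matrix(values)
  if (is.null(protein_ids)) stop("protein ids are required", call. = FALSE)
  if (anyDuplicated(protein_ids))
    stop("protein ids must be unique", call. = FALSE)
  if (length(protein_ids) != ncol(values))
    stop("protein_ids must match the number of columns", call. = FALSE)
  colnames(values) <- protein_ids
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("row_%04d", seq_len(nrow(values)))
  if (!is.null(panel)) {
    if (is.null(names(panel))) names(panel) <- protein_ids
    panel <- panel[protein_ids]
  }
  structure(list(values = values, protein_ids = protein_ids, panel = panel),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d participants x %d proteins (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

# row/column subsetting that preserves the container
.pm_rows <- function(pm, idx) {
  protein_matrix(pm$values[idx, , drop = FALSE], pm$protein_ids, pm$panel)
}
.pm_cols <- function(pm, keep) {
  protein_matrix(pm$values[, keep, drop = FALSE],
                 pm$protein_ids[keep],
                 if (is.null(pm$panel)) NULL else pm$panel[keep])
}

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s is missing mandatory column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read and write participant covariate/outcome tables
#'
#' `read_cohort()` reads a delimited (TSV or CSV, auto-detected) participant
#' table. Numeric columns with unparseable cells have those cells set missing,
#' with a message reporting the count. Duplicated participant ids and missing
#' mandatory columns (`participant_id`, `age`, `sex`) are format errors.
#'
#' @param path file path.
#' @return A data.frame, one row per participant.
#' @export
read_cohort <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  .require_columns(df, c("participant_id", "age", "sex"), "cohort table")
  if (anyDuplicated(df$participant_id))
    stop("duplicated participant_id in cohort table", call. = FALSE)
  num_cols <- setdiff(names(df), c("participant_id", "diagnosis"))
  n_bad <- 0L
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) {
      old_na <- sum(is.na(df[[cl]]))
      df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
      n_bad <- n_bad + (sum(is.na(df[[cl]])) - old_na)
    }
  }
  if (n_bad > 0)
    message(sprintf("read_cohort: %d unparseable cell(s) set to missing", n_bad))
  df
}

#' @rdname read_cohort
#' @param cohort a cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write NPX protein matrices
#'
#' `read_matrix()` reads a delimited matrix whose first column is
#' `participant_id` and remaining columns are proteins; empty or unparseable
#' cells become missing (counted in a message).
#'
#' @param path file path.
#' @return A [protein_matrix()].
#' @export
read_matrix <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  .require_columns(df, "participant_id", "protein matrix")
  if (anyDuplicated(df$participant_id))
    stop("duplicated participant_id in protein matrix", call. = FALSE)
  ids <- df$participant_id
  vals <- df[, setdiff(names(df), "participant_id"), drop = FALSE]
  n_bad <- 0L
  for (cl in names(vals)) {
    if (!is.numeric(vals[[cl]])) {
      old_na <- sum(is.na(vals[[cl]]))
      vals[[cl]] <- suppressWarnings(as.numeric(vals[[cl]]))
      n_bad <- n_bad + (sum(is.na(vals[[cl]])) - old_na)
    }
  }
  if (n_bad > 0)
    message(sprintf("read_matrix: %d unparseable cell(s) set to missing", n_bad))
  m <- as.matrix(vals)
  rownames(m) <- ids
  protein_matrix(m)
}

#' @rdname read_matrix
#' @param matrix a [protein_matrix()].
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "protein_matrix"))
  df <- data.frame(participant_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Per-protein missing frequency
#'
#' @param matrix a [protein_matrix()].
#' @return Named numeric vector: fraction of participants missing per protein.
#' @export
missing_frequency <- function(matrix) {
  stopifnot(inherits(matrix, "protein_matrix"))
  colMeans(is.na(matrix$values))
}

#' Detectability filter
#'
#' Keeps proteins whose missing frequency is strictly below `max_missing`
#' (the conventional threshold is 75%). Protein order is preserved, and the
#' filter is idempotent.
#'
#' @param matrix a [protein_matrix()].
#' @param max_missing maximum allowed missing fraction, in \[0, 1\].
#' @return A filtered [protein_matrix()]; a warning (not an error) if no
#'   protein survives.
#' @export
detectability_filter <- function(matrix, max_missing = 0.75) {
  stopifnot(inherits(matrix, "protein_matrix"),
            max_missing >= 0, max_missing <= 1)
  mf <- missing_frequency(matrix)
  # strict "<" threshold; fully observed proteins always survive, including
  # the max_missing = 0 boundary
  keep <- mf < max_missing | mf == 0
  if (!any(keep)) warning("detectability_filter removed every protein")
  .pm_cols(matrix, keep)
}

#' Random training/test split
#'
#' Splits the cohort (and the congruent protein matrix) into disjoint,
#' exhaustive training and test sets. The test size is `round(n *
#' test_fraction)`; simple random sampling by default, optionally stratified.
#'
#' @param cohort participant table with unique `participant_id`.
#' @param matrix a [protein_matrix()] with matching rows.
#' @param test_fraction fraction held out, in (0, 1).
#' @param seed integer seed; same seed gives identical partitions.
#' @param stratify_by optional cohort column name to stratify on (e.g.
#'   `"diagnosis"`); off by default.
#' @return A list with `train` and `test`, each a list of `cohort` and
#'   `matrix`.
#' @export
train_test_split <- function(cohort, matrix, test_fraction = 0.2, seed = 1L,
                             stratify_by = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            inherits(matrix, "protein_matrix"),
            nrow(cohort) == nrow(matrix$values))
  n <- nrow(cohort)
  set.seed(seed)
  if (is.null(stratify_by)) {
    test_idx <- sort(sample.int(n, round(n * test_fraction)))
  } else {
    strata <- split(seq_len(n), cohort[[stratify_by]])
    test_idx <- sort(unlist(lapply(strata, function(ix) {
      if (length(ix) == 0) return(integer(0))
      sample(ix, round(length(ix) * test_fraction))
    }), use.names = FALSE))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  list(
    train = list(cohort = cohort[train_idx, , drop = FALSE],
                 matrix = .pm_rows(matrix, train_idx)),
    test = list(cohort = cohort[test_idx, , drop = FALSE],
                matrix = .pm_rows(matrix, test_idx))
  )
}
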