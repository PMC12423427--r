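#' Read a delimited numeric matrix
#'
#' Matrix files are plain whitespace/tab/comma-delimited text without
#' header; row i is source ROI i.
#'
#' @param path file path.
#' @return numeric matrix.
#' @keywords internal
read_matrix_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Write a numeric matrix as delimited text
#' @param m numeric matrix.
#' @param path file path; tab-delimited, no header.
#' @keywords internal
write_matrix_file <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble one subject's connectome
#'
#' Builds a `subject_connectome` from a structural connectivity (SC) matrix
#' plus either a functional connectivity (FC) Fisher-z matrix or an ROI
#' time-series matrix. SC holds tractography connection probabilities
#' `w_ij` in `[0, 1]` (directed, zero diagonal); FC is symmetric with the
#' diagonal never consumed downstream.
#'
#' @param subject_id subject identifier.
#' @param sc n_roi x n_roi nonnegative matrix, or a path to one.
#' @param fc optional symmetric Fisher-z matrix or path.
#' @param timeseries optional T x n_roi matrix or path. If `fc` is missing
#'   it stays empty (`NULL`) for downstream construction via
#'   [fc_from_timeseries()].
#' @param scheme a `parcellation_scheme`; matrix order must match its ROIs.
#' @return object of class `subject_connectome`: list with `subject_id`,
#'   `sc`, `fc` (possibly `NULL`), `timeseries` (possibly `NULL`).
#' @export
subject_connectome <- function(subject_id, sc, fc = NULL, timeseries = NULL,
                               scheme) {
  stopifnot(inherits(scheme, "parcellation_scheme"))
  n <- nrow(scheme)
  if (is.character(sc)) sc <- read_matrix_file(sc)
  if (is.character(fc)) fc <- read_matrix_file(fc)
  if (is.character(timeseries)) timeseries <- read_matrix_file(timeseries)
  if (!is.matrix(sc) || nrow(sc) != n || ncol(sc) != n)
    stop("sc must be a ", n, "x", n, " matrix matching the scheme")
  if (!all(is.finite(sc))) stop("sc contains non-finite entries")
  if (any(sc < 0)) stop("sc has negative weights")
  if (any(sc > 1)) stop("sc has weights > 1 (expects connection probabilities)")
  if (any(diag(sc) != 0)) stop("sc diagonal must be zero")
  if (!is.null(fc)) {
    if (!is.matrix(fc) || nrow(fc) != n || ncol(fc) != n)
      stop("fc must be a ", n, "x", n, " matrix matching the scheme")
    if (!all(is.finite(fc))) stop("fc contains non-finite entries")
    if (max(abs(fc - t(fc))) > 1e-8)
      stop("fc is not symmetric")
    diag(fc) <- 0  # never consumed; normalized for round-trips
  }
  if (!is.null(timeseries)) {
    if (!is.matrix(timeseries) || ncol(timeseries) != n)
      stop("timeseries must have one column per ROI (", n, ")")
    if (!all(is.finite(timeseries))) stop("timeseries has non-finite entries")
  }
  structure(list(subject_id = as.character(subject_id), sc = sc, fc = fc,
                 timeseries = timeseries),
            class = "subject_connectome")
}

#' Read one subject's connectome from a per-subject directory
#'
#' Expects the layout `<dir>/sc.tsv` plus `<dir>/fc.tsv` and/or
#' `<dir>/ts.tsv` (delimited matrices, no header).
#'
#' @param dir per-subject directory; its basename is the subject id unless
#'   `subject_id` is given.
#' @param scheme a `parcellation_scheme`.
#' @param subject_id optional explicit id.
#' @return a `subject_connectome`.
#' @export
read_connectome <- function(dir, scheme, subject_id = basename(dir)) {
  scp <- file.path(dir, "sc.tsv")
  fcp <- file.path(dir, "fc.tsv")
  tsp <- file.path(dir, "ts.tsv")
  if (!file.exists(scp)) stop("missing sc.tsv in ", dir)
  if (!file.exists(fcp) && !file.exists(tsp))
    stop("need fc.tsv or ts.tsv in ", dir)
  subject_connectome(subject_id, scp,
                     fc = if (file.exists(fcp)) fcp else NULL,
                     timeseries = if (file.exists(tsp)) tsp else NULL,
                     scheme = scheme)
}

#' Write a subject connectome to a per-subject directory
#' @param x a `subject_connectome`.
#' @param dir output directory (created if needed).
#' @export
write_connectome <- function(x, dir) {
  stopifnot(inherits(x, "subject_connectome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_file(x$sc, file.path(dir, "sc.tsv"))
  if (!is.null(x$fc)) write_matrix_file(x$fc, file.path(dir, "fc.tsv"))
  if (!is.null(x$timeseries))
    write_matrix_file(x$timeseries, file.path(dir, "ts.tsv"))
  invisible(dir)
}

#' @export
print.subject_connectome <- function(x, ...) {
  cat("Subject", x$subject_id, "-", nrow(x$sc), "ROIs; fc:",
      if (is.null(x$fc)) "absent" else "present", "; timeseries:",
      if (is.null(x$timeseries)) "absent" else
        paste0(nrow(x$timeseries), " frames"), "\n")
  invisible(x)
}

#' Write tidy result tables to CSV
#'
#' Results (association tables, coupling tables, summaries) are written in
#' full double precision so that a write/read round-trip is lossless to at
#' least 12 significant digits.
#'
#' @param results nonempty data.frame.
#' @param path output CSV path.
#' @param overwrite allow clobbering an existing file.
#' @export
write_results <- function(results, path, overwrite = FALSE) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a nonempty data.frame")
  if (file.exists(path) && !overwrite)
    stop("file exists (use overwrite = TRUE): ", path)
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA_character_, sprintf("%.15g", v))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back a tidy result CSV written by [write_results()]
#' @param path CSV path.
#' @param numeric_cols columns to coerce to numeric; by default every
#'   column that parses fully as a number.
#' @return data.frame.
#' @export
read_results <- function(path, numeric_cols = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (is.null(numeric_cols)) {
    numeric_cols <- names(tab)[vapply(tab, function(v) {
      if (!is.character(v)) return(is.numeric(v))
      ok <- suppressWarnings(as.numeric(v))
      all(is.na(v) | !is.na(ok))
    }, logical(1))]
  }
  for (cl in numeric_cols) tab[[cl]] <- as.numeric(tab[[cl]])
  tab
}

#' Read a cohort table CSV
#'
#' Schema: `subject_id`, `age` (years), `sex` (`female`/`male`),
#' `education` (years), risk flags (`hypertension`, `diabetes`,
#' `hypercholesterolemia`, `smoking`, `drinking`; 0/1), `pwmh`, `dwmh`
#' (Fazekas 0-3), `wmh_volume` (mL), cognitive score columns, and optional
#' follow-up columns (`*_fu`, `follow_up_duration` in years).
#'
#' @param path CSV path.
#' @return validated cohort data.frame with a derived `severity` column.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(tab)
}

#' Validate a cohort table and derive severity
#' @param tab cohort data.frame.
#' @return the table with `severity` consistent with the Fazekas rule.
#' @export
validate_cohort <- function(tab) {
  need <- c("subject_id", "age", "sex", "pwmh", "dwmh", "wmh_volume")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$subject_id)) stop("duplicate subject_id in cohort")
  if (!all(tab$sex %in% c("female", "male"))) stop("sex must be female/male")
  if (any(tab$wmh_volume < 0, na.rm = TRUE)) stop("wmh_volume must be >= 0")
  tab$severity <- classify_severity(tab$pwmh, tab$dwmh)
  tab
}
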