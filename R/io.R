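#' Read a long-format weight-readings file
#'
#' Reads a CSV with header columns `patient_id`, `day` and `weight`, one row
#' per submitted reading. `day` is the 0-based number of days since
#' enrolment; `weight` is the reported weight in pounds (whole numbers in
#' keypad-entered data, possibly fractional in simulated data).
#'
#' Rows with a missing or non-positive weight, or a missing or negative day,
#' are rejected with a warning that names the offending rows. A duplicate
#' (patient, day) pair is an error: the expected data model has at most one
#' reading per patient per calendar day, and silently collapsing duplicates
#' would bias every per-patient proportion downstream.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `patient_id` (character), `day` (integer)
#'   and `weight` (numeric), sorted by patient then day.
#' @seealso [write_weight_readings()], [read_covariates()]
#' @export
read_weight_readings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("readings file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  df$patient_id <- as.character(df$patient_id)
  df$day <- suppressWarnings(as.numeric(df$day))
  df$weight <- suppressWarnings(as.numeric(df$weight))
  bad <- is.na(df$day) | df$day < 0 | is.na(df$weight) | df$weight <= 0
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with non-positive weight or negative/missing day: rows %s",
                    sum(bad), paste(utils::head(which(bad), 20L), collapse = ", ")),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(df[c("patient_id", "day")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("duplicate reading for patient '%s' on day %d (row %d)",
                 df$patient_id[i], as.integer(df$day[i]), i), call. = FALSE)
  }
  df$day <- as.integer(df$day)
  df <- df[order(df$patient_id, df$day), , drop = FALSE]
  rownames(df) <- NULL
  tibble::as_tibble(df)
}

#' Write weight readings to CSV
#'
#' Inverse of [read_weight_readings()]; the round trip preserves every
#' reading exactly (weights are written at full precision).
#'
#' @param readings Tibble with columns `patient_id`, `day`, `weight`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_readings <- function(readings, path) {
  stopifnot(all(c("patient_id", "day", "weight") %in% names(readings)))
  utils::write.csv(readings[c("patient_id", "day", "weight")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a patient covariate table
#'
#' Reads a CSV with a `patient_id` column plus one column per covariate.
#' Empty cells become `NA` (missing); binary covariates are coded 0/1.
#' Missing values are handled available-case, covariate by covariate, by
#' the summarising functions.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `patient_id` (character) and numeric covariate
#'   columns.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df))
    stop("covariates file is missing the patient_id column", call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  for (nm in setdiff(names(df), "patient_id"))
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in covariates file", call. = FALSE)
  tibble::as_tibble(df[order(df$patient_id), , drop = FALSE])
}

#' @rdname read_covariates
#' @param covariates Tibble as returned by [read_covariates()].
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serialises any pipeline result (lists, tibbles, S3 result objects) to a
#' structured JSON report. Numeric fields round-trip at full double
#' precision.
#'
#' @param results Pipeline result object (list-like).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(results, path) {
  results <- strip_classes(results)
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

# jsonlite serialises plain lists/data.frames most predictably; drop custom
# S3 classes recursively before writing.
strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write a simulated cohort to disk
#'
#' Writes the three plain-text artefacts of a cohort: `readings.csv` and
#' `covariates.csv` in the formats [read_weight_readings()] and
#' [read_covariates()] read, and `ground_truth.csv` with columns
#' `patient_id`, `is_edp`, `n_rounded_days`.
#'
#' @param cohort An `edp_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "edp_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_weight_readings(cohort$readings, file.path(dir, "readings.csv"))
  if (!is.null(cohort$covariates))
    write_covariates(cohort$covariates, file.path(dir, "covariates.csv"))
  truth <- cohort$truth
  truth$is_edp <- as.integer(truth$is_edp)
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
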