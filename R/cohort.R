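#' Configuration for a synthetic telemonitoring cohort
#'
#' Describes the data-generating process for a cohort of hypothetical
#' heart-failure patients: a Gaussian random walk for the true daily
#' weight, a labelled fraction of patients with end-digit preference who
#' round a fixed fraction of their reports to the nearest multiple of
#' five, and optional covariate distributions that differ between the EDP
#' and NEDP groups.
#'
#' @param n_patients Number of patients.
#' @param edp_fraction Fraction of patients labelled EDP; exactly
#'   `round(edp_fraction * n_patients)` patients receive the label.
#' @param round_fraction `q`, the fraction of an EDP patient's reporting
#'   days on which the report is rounded. Under the default fixed-count
#'   model exactly `round(q * n)` of `n` days are rounded; the
#'   `"bernoulli"` model rounds each day independently with probability
#'   `q`.
#' @param sd_daily Standard deviation of the daily weight change in
#'   pounds (0 gives constant weights), or `"limiting"` for the
#'   high-volatility limit in which successive integer residues are iid
#'   uniform on `{0, 1, 2, 3, 4}`.
#' @param n_days Reporting days per patient: a single integer (trial mean
#'   162), an integer vector of length `n_patients`, or a function
#'   `f(n_patients)` returning one.
#' @param start_weight Range (length-2) of the uniform distribution of
#'   starting weights in pounds; the default 120-220 makes the starting
#'   residue uniform on `{0, ..., 4}`.
#' @param covariate_effects Optional tibble with columns `covariate`,
#'   `type` (`"binary"` or `"continuous"`), `edp`, `nedp` (prevalence for
#'   binary, mean for continuous) and `sd` (continuous only).
#' @param rounding_model `"fixed"` (default) or `"bernoulli"`.
#' @param report_style How non-rounded days report the true weight:
#'   `"floor"` (integer part, default) or `"round"` (nearest integer,
#'   half-up).
#' @param seed Optional integer seed; fixed seeds give byte-identical
#'   cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, edp_fraction = 0.15,
                          round_fraction = 0.3, sd_daily = 1,
                          n_days = 162L, start_weight = c(120, 220),
                          covariate_effects = NULL,
                          rounding_model = c("fixed", "bernoulli"),
                          report_style = c("floor", "round"),
                          seed = NULL) {
  rounding_model <- match.arg(rounding_model)
  report_style <- match.arg(report_style)
  if (edp_fraction < 0 || edp_fraction > 1)
    stop("`edp_fraction` must be in [0, 1]", call. = FALSE)
  if (round_fraction < 0 || round_fraction > 1)
    stop("`round_fraction` must be in [0, 1]", call. = FALSE)
  limiting <- identical(sd_daily, "limiting")
  if (!limiting) {
    if (!is.numeric(sd_daily) || length(sd_daily) != 1L || sd_daily < 0)
      stop("`sd_daily` must be a non-negative number or \"limiting\"",
           call. = FALSE)
  }
  if (!is.null(covariate_effects)) {
    need <- c("covariate", "type", "edp", "nedp")
    if (!all(need %in% names(covariate_effects)))
      stop("covariate_effects needs columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    if (any(covariate_effects$type == "continuous") &&
        !"sd" %in% names(covariate_effects))
      stop("continuous covariate_effects need an `sd` column", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), edp_fraction = edp_fraction,
         round_fraction = round_fraction, sd_daily = sd_daily,
         limiting = limiting, n_days = n_days, start_weight = start_weight,
         covariate_effects = covariate_effects,
         rounding_model = rounding_model, report_style = report_style,
         seed = seed),
    class = "cohort_config"
  )
}

#' True daily weight path for one patient
#'
#' Gaussian random walk: `w_t = w_{t-1} + N(0, sd_daily^2)`, zero drift.
#' `sd_daily = 0` gives a constant path. In limiting mode each day's
#' weight is an independent uniform integer on 120-224 pounds: successive
#' residues are then iid and exactly uniform modulo 5 -- the regime a
#' high-volatility walk converges to -- and, because the range spans 105 =
#' 3 x 5 x 7 values, also exactly uniform modulo 3 and 7, which keeps the
#' divisor-specificity controls clean. The starting residue is uniform on
#' `{0, ..., 4}` in every mode.
#'
#' @param n_days Number of reporting days.
#' @param sd_daily Non-negative daily-change standard deviation, or
#'   `"limiting"`.
#' @param start Starting weight in pounds (ignored in limiting mode).
#' @return Numeric vector of `n_days` true weights.
#' @export
generate_true_weights <- function(n_days, sd_daily, start = 170) {
  stopifnot(n_days >= 1)
  if (identical(sd_daily, "limiting"))
    return(120 + sample(0:104, n_days, replace = TRUE))
  if (!is.numeric(sd_daily) || sd_daily < 0)
    stop("`sd_daily` must be non-negative or \"limiting\"", call. = FALSE)
  if (sd_daily == 0 || n_days == 1L) return(rep(start, n_days))
  start + c(0, cumsum(stats::rnorm(n_days - 1L, 0, sd_daily)))
}

# nearest multiple of five; exact midpoints (x == 2.5 mod 5) round up
round_to_five <- function(x) 5 * floor(x / 5 + 0.5)

#' Turn a true weight path into reported values
#'
#' Non-rounded days report the integer part of the true weight (or the
#' nearest integer under `report_style = "round"`). For an EDP patient,
#' rounded days -- exactly `round(q * n)` of them under the fixed-count
#' model, chosen uniformly at random and independently of the weight
#' values -- report the nearest multiple of five instead. NEDP patients
#' never round.
#'
#' @param true_weights Numeric vector of true weights.
#' @param is_edp Logical: does this patient round?
#' @param q Fraction of days rounded (see [cohort_config()]).
#' @param rounding_model `"fixed"` or `"bernoulli"`.
#' @param report_style `"floor"` or `"round"`.
#' @return A list with `reported` (numeric vector) and `rounded_days`
#'   (sorted integer indices, 1-based, of the rounded entries; empty for
#'   NEDP patients).
#' @examples
#' apply_reporting(rep(142.3, 4), is_edp = TRUE, q = 1)$reported  # all 140
#' @export
apply_reporting <- function(true_weights, is_edp, q,
                            rounding_model = c("fixed", "bernoulli"),
                            report_style = c("floor", "round")) {
  rounding_model <- match.arg(rounding_model)
  report_style <- match.arg(report_style)
  if (q < 0 || q > 1) stop("`q` must be in [0, 1]", call. = FALSE)
  n <- length(true_weights)
  reported <- if (report_style == "floor") floor(true_weights)
  else floor(true_weights + 0.5)
  rounded <- integer(0)
  if (isTRUE(is_edp) && q > 0) {
    if (rounding_model == "fixed") {
      m <- round(q * n)
      if (m > 0) rounded <- sort(sample.int(n, m))
    } else {
      rounded <- which(stats::runif(n) < q)
    }
    reported[rounded] <- round_to_five(true_weights[rounded])
  }
  list(reported = reported, rounded_days = rounded)
}

#' Generate a synthetic telemonitoring cohort
#'
#' Draws a full cohort under a [cohort_config()]: EDP labels, true weight
#' paths, reported values, optional covariates, and the ground truth
#' needed to score any downstream estimator.
#'
#' Draw order (for reproducibility with a fixed seed): EDP labels, then
#' per patient in id order the reporting-day count (if random), path and
#' rounded-day draws, then covariates column by column.
#'
#' @param config A [cohort_config()].
#' @return An object of class `edp_cohort`: a list with `readings`
#'   (tibble `patient_id`, `day`, `weight` -- days 0-based), `covariates`
#'   (tibble or `NULL`), `truth` (tibble `patient_id`, `is_edp`,
#'   `n_rounded_days`), `rounding_days` (tibble `patient_id`, `day` of
#'   every rounded report) and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(20, seed = 1, n_days = 30))
#' table(coh$truth$is_edp)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  np <- config$n_patients
  ids <- sprintf("P%0*d", max(4L, nchar(np)), seq_len(np))

  n_edp <- round(config$edp_fraction * np)
  is_edp <- rep(FALSE, np)
  if (n_edp > 0) is_edp[sample.int(np, n_edp)] <- TRUE

  nd <- config$n_days
  if (is.function(nd)) nd <- nd(np)
  if (length(nd) == 1L) nd <- rep(as.integer(nd), np)
  if (length(nd) != np) stop("`n_days` must be scalar, length n_patients, or a function",
                             call. = FALSE)

  per <- vector("list", np)
  for (i in seq_len(np)) {
    if (config$limiting) {
      w <- generate_true_weights(nd[i], "limiting")
    } else {
      start <- stats::runif(1, config$start_weight[1L], config$start_weight[2L])
      w <- generate_true_weights(nd[i], config$sd_daily, start)
    }
    rep_i <- apply_reporting(w, is_edp[i], config$round_fraction,
                             config$rounding_model, config$report_style)
    per[[i]] <- rep_i
  }

  readings <- tibble::tibble(
    patient_id = rep(ids, nd),
    day = unlist(lapply(nd, function(k) seq_len(k) - 1L), use.names = FALSE),
    weight = unlist(lapply(per, `[[`, "reported"), use.names = FALSE))

  n_rounded <- vapply(per, function(p) length(p$rounded_days), integer(1))
  truth <- tibble::tibble(patient_id = ids, is_edp = is_edp,
                          n_rounded_days = n_rounded)
  rounding_days <- tibble::tibble(
    patient_id = rep(ids, n_rounded),
    day = unlist(lapply(per, function(p) p$rounded_days - 1L),
                 use.names = FALSE))

  covariates <- NULL
  ce <- config$covariate_effects
  if (!is.null(ce)) {
    covariates <- tibble::tibble(patient_id = ids)
    for (j in seq_len(nrow(ce))) {
      mu <- ifelse(is_edp, ce$edp[j], ce$nedp[j])
      covariates[[ce$covariate[j]]] <- if (ce$type[j] == "binary")
        stats::rbinom(np, 1L, mu)
      else stats::rnorm(np, mu, ce$sd[j])
    }
  }

  structure(list(readings = readings, covariates = covariates,
                 truth = truth, rounding_days = rounding_days,
                 config = config),
            class = "edp_cohort")
}

#' @export
print.edp_cohort <- function(x, ...) {
  cat(sprintf("<edp_cohort> %d patients, %d readings, %d labelled EDP\n",
              nrow(x$truth), nrow(x$readings), sum(x$truth$is_edp)))
  invisible(x)
}
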