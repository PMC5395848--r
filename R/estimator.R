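#' Subtraction estimator of the number of patients with end-digit preference
#'
#' Patients without end-digit preference are equally likely to land in any
#' of the subgroups `A0`..`A4` by chance, so the mean size of `A1`-`A4`
#' estimates the chance component of `A0`. The estimated number of EDP
#' patients is therefore
#' \deqn{\hat N_{EDP} = n_0 - \frac{1}{4}\sum_{i=1}^{4} n_i,}
#' a lower bound (EDP patients missed by `A0`, or leaking into `A1`-`A4`,
#' both bias it downward). A negative estimate is reported as-is with
#' `negative = TRUE`, never clipped.
#'
#' @param table A [subgroup_table()].
#' @param patients_analysed Denominator for the EDP fraction: the number of
#'   patients who submitted any data (not only subgroup members). Defaults
#'   to `table$n_patients` when recorded there.
#' @return An object of class `edp_estimate`: `edp_count` (real),
#'   `edp_count_rounded`, `edp_fraction`, `patients_analysed`, `sizes`,
#'   `negative` flag.
#' @examples
#' edp_count(subgroup_table(c(212, 96, 107, 130, 95)), 707)
#' @export
edp_count <- function(table, patients_analysed = table$n_patients) {
  stopifnot(inherits(table, "subgroup_table"))
  if (is.na(patients_analysed) || patients_analysed <= 0)
    stop("`patients_analysed` must be a positive count", call. = FALSE)
  s <- table$sizes
  count <- unname(s[1L] - mean(s[-1L]))
  structure(
    list(edp_count = count, edp_count_rounded = round(count),
         edp_fraction = count / patients_analysed,
         patients_analysed = patients_analysed,
         sizes = s, negative = count < 0),
    class = "edp_estimate"
  )
}

#' @export
print.edp_estimate <- function(x, ...) {
  cat(sprintf("<edp_estimate> %.1f EDP patients (%.1f%% of %d analysed)%s\n",
              x$edp_count, 100 * x$edp_fraction, x$patients_analysed,
              if (x$negative) " [NEGATIVE]" else ""))
  invisible(x)
}

#' Estimated number of patients without end-digit preference
#'
#' The NEDP count is the number of patients remaining in `A0` once the
#' estimated EDP patients are removed, plus all members of `A1`-`A4`:
#' `(n0 - edp) + n1 + n2 + n3 + n4`.
#'
#' @param table A [subgroup_table()].
#' @param edp Estimated EDP count: a number or an `edp_estimate`.
#' @return The estimated NEDP count (real).
#' @examples
#' nedp_count(subgroup_table(c(212, 96, 107, 130, 95)), 105)
#' @export
nedp_count <- function(table, edp) {
  stopifnot(inherits(table, "subgroup_table"))
  if (inherits(edp, "edp_estimate")) edp <- edp$edp_count
  s <- table$sizes
  if (edp > s[1L])
    stop("EDP count exceeds the size of A0", call. = FALSE)
  unname((s[1L] - edp) + sum(s[-1L]))
}

#' Pooled characteristic of patients without end-digit preference
#'
#' Estimates a baseline characteristic of NEDP patients as the pooled
#' (size-weighted) mean across subgroups `A1`-`A4`:
#' \eqn{\sum_{i=1}^4 n_i x_i / \sum_{i=1}^4 n_i}.
#'
#' @param means Numeric vector of per-subgroup means `x0`..`x4` (ordered as
#'   the sizes; `x0` is ignored here but kept for a uniform signature).
#' @param sizes Numeric vector of subgroup sizes `n0`..`n4`.
#' @return The pooled NEDP mean.
#' @examples
#' nedp_mean(c(62.1, 66.1, 65.1, 63.1, 62.1), c(212, 96, 107, 130, 95))
#' @export
nedp_mean <- function(means, sizes) {
  stopifnot(length(means) == length(sizes), length(sizes) >= 2L)
  n <- sizes[-1L]; x <- means[-1L]
  ok <- !is.na(x) & n > 0
  if (sum(n[ok]) <= 0) stop("no members in subgroups A1-A4", call. = FALSE)
  sum(n[ok] * x[ok]) / sum(n[ok])
}

#' Weighted-average characteristic of patients with end-digit preference
#'
#' Subtracts the chance (NEDP) contribution from the `A0` total of a
#' characteristic and divides by the estimated EDP count:
#' \deqn{\hat x_{EDP} = \frac{n_0 x_0 - \frac14\sum_{i=1}^4 n_i x_i}
#'                           {n_0 - \frac14\sum_{i=1}^4 n_i}.}
#' For a 0/1 covariate, pass member proportions as the means (equivalently
#' `count/size`); the result is the EDP proportion.
#'
#' @inheritParams nedp_mean
#' @return The estimated EDP mean, or `NA` (with a warning) when the
#'   estimated EDP count is not positive.
#' @examples
#' edp_mean(c(62.1, 66.1, 65.1, 63.1, 62.1), c(212, 96, 107, 130, 95))
#' @export
edp_mean <- function(means, sizes) {
  stopifnot(length(means) == length(sizes), length(sizes) >= 2L)
  den <- sizes[1L] - mean(sizes[-1L])
  if (is.na(means[1L]) || anyNA(means[-1L])) return(NA_real_)
  if (den <= 0) {
    warning("estimated EDP count is not positive; EDP mean unavailable",
            call. = FALSE)
    return(NA_real_)
  }
  unname((sizes[1L] * means[1L] - mean(sizes[-1L] * means[-1L])) / den)
}

#' Patient-level percentile bootstrap for the EDP estimators
#'
#' Resamples patients (their subgroup assignment together with their
#' covariates) with replacement to the original size, recomputes the
#' subgroup table and every estimator on each replica, and reports
#' percentile confidence intervals. Subgroup assignment is a deterministic
#' function of a patient's readings, so resampling assignment rows is
#' exactly equivalent to resampling whole reading series and re-running
#' the per-patient tests.
#'
#' Replicates where an estimator is unavailable (estimated EDP count not
#' positive, or an empty `A1`-`A4` pool) are excluded from that
#' statistic's interval and counted in `n_excluded`.
#'
#' @param assignments Output of [assign_subgroups()].
#' @param covariates Optional covariate tibble; adds `edp_mean_<cov>` and
#'   `nedp_mean_<cov>` statistics.
#' @param patients_analysed Denominator for the EDP fraction (default: all
#'   patients in `assignments`).
#' @param B Number of bootstrap replicates (>= 100 recommended for
#'   reporting).
#' @param seed Optional seed for reproducible intervals.
#' @param conf Confidence level (default 0.95).
#' @return A tibble with one row per statistic: `statistic`, `estimate`
#'   (point estimate on the full data), `lower`, `upper`, `B`,
#'   `n_excluded`.
#' @export
edp_bootstrap <- function(assignments, covariates = NULL,
                          patients_analysed = nrow(assignments),
                          B = 1000L, seed = NULL, conf = 0.95) {
  if (nrow(assignments) < 2L)
    stop("need at least two patients to bootstrap", call. = FALSE)
  if (B < 1L) stop("`B` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- membership_matrix(assignments)
  np <- nrow(m)
  cov_names <- character(0)
  vals <- NULL
  if (!is.null(covariates)) {
    cov_names <- setdiff(names(covariates), "patient_id")
    idx <- match(rownames(m), covariates$patient_id)
    vals <- as.matrix(covariates[idx, cov_names, drop = FALSE])
  }

  stat_one <- function(rows) {
    mm <- m[rows, , drop = FALSE]
    sizes <- colSums(mm)
    count <- sizes[1L] - mean(sizes[-1L])
    out <- c(edp_count = unname(count),
             edp_fraction = unname(count / patients_analysed),
             nedp_count = unname((sizes[1L] - count) + sum(sizes[-1L])))
    for (ci in seq_along(cov_names)) {
      v <- vals[rows, ci]
      ok <- !is.na(v)
      xbar <- vapply(seq_len(ncol(mm)), function(j) {
        sel <- mm[, j] & ok
        if (any(sel)) mean(v[sel]) else NA_real_
      }, numeric(1))
      e <- if (count > 0 && !anyNA(xbar))
        (sizes[1L] * xbar[1L] - mean(sizes[-1L] * xbar[-1L])) / count
      else NA_real_
      nw <- sizes[-1L]; xw <- xbar[-1L]
      keep <- !is.na(xw) & nw > 0
      ne <- if (sum(nw[keep]) > 0) sum(nw[keep] * xw[keep]) / sum(nw[keep])
      else NA_real_
      out[paste0("edp_mean_", cov_names[ci])] <- e
      out[paste0("nedp_mean_", cov_names[ci])] <- ne
    }
    out
  }

  point <- stat_one(seq_len(np))
  reps <- matrix(NA_real_, nrow = B, ncol = length(point),
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(B))
    reps[b, ] <- stat_one(sample.int(np, np, replace = TRUE))

  a <- (1 - conf) / 2
  rows <- lapply(seq_along(point), function(j) {
    x <- reps[, j]
    n_ex <- sum(is.na(x))
    if (n_ex == B)
      return(tibble::tibble(statistic = names(point)[j],
                            estimate = point[j], lower = NA_real_,
                            upper = NA_real_, B = B, n_excluded = n_ex))
    q <- stats::quantile(x, c(a, 1 - a), na.rm = TRUE, names = FALSE)
    tibble::tibble(statistic = names(point)[j], estimate = unname(point[j]),
                   lower = q[1L], upper = q[2L], B = B, n_excluded = n_ex)
  })
  out <- do.call(rbind, rows)
  if (all(out$n_excluded == out$B))
    warning("all bootstrap replicates were unavailable", call. = FALSE)
  out
}

#' Full EDP analysis of a readings table
#'
#' Convenience orchestrator: assigns subgroups, tabulates sizes, applies
#' the subtraction and weighted-average estimators, and (optionally)
#' bootstraps confidence intervals for every statistic.
#'
#' @param readings Readings tibble.
#' @param covariates Optional covariate tibble.
#' @param config An [edp_config()].
#' @param patients_analysed Denominator for the EDP fraction; defaults to
#'   the number of distinct patients in `readings`.
#' @param bootstrap Compute bootstrap intervals (uses
#'   `config$bootstrap_reps` and `config$seed`).
#' @return A list of class `edp_analysis`: `assignments`, `table`,
#'   `estimate` (an `edp_estimate`), `nedp_count`, `characteristics`
#'   (per-covariate EDP/NEDP means, if covariates given), `bootstrap`
#'   (tibble of intervals, if requested) and `config`.
#' @export
edp_analysis <- function(readings, covariates = NULL,
                         config = edp_config(),
                         patients_analysed = NULL, bootstrap = TRUE) {
  asg <- assign_subgroups(readings, config)
  if (is.null(patients_analysed)) patients_analysed <- nrow(asg)
  tab <- subgroup_sizes(asg)
  est <- edp_count(tab, patients_analysed)
  ned <- nedp_count(tab, est)
  chars <- NULL
  if (!is.null(covariates)) {
    cs <- covariate_summaries(asg, covariates)
    cov_names <- unique(cs$covariate)
    chars <- do.call(rbind, lapply(cov_names, function(cv) {
      # rows are emitted in class order A0..A(d-1) within each covariate
      xi <- cs$mean[cs$covariate == cv]
      tibble::tibble(covariate = cv,
                     edp_mean = edp_mean(xi, tab$sizes),
                     nedp_mean = nedp_mean(xi, tab$sizes))
    }))
  }
  boot <- NULL
  if (bootstrap)
    boot <- edp_bootstrap(asg, covariates,
                          patients_analysed = patients_analysed,
                          B = config$bootstrap_reps, seed = config$seed)
  structure(list(assignments = asg, table = tab, estimate = est,
                 nedp_count = ned, characteristics = chars,
                 bootstrap = boot, config = config),
            class = "edp_analysis")
}

#' @export
print.edp_analysis <- function(x, ...) {
  print(x$table)
  print(x$estimate)
  cat(sprintf("  estimated NEDP patients: %.1f\n", x$nedp_count))
  if (!is.null(x$characteristics)) {
    cat("  characteristics (EDP vs NEDP):\n")
    print(x$characteristics)
  }
  invisible(x)
}
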