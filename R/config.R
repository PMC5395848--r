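#' Analysis configuration
#'
#' Bundles the tunable parameters shared by all pipeline stages: the
#' per-patient test level, the divisor defining residue classes, bootstrap
#' settings, alert thresholds and the choice of per-class proportion test.
#'
#' @param alpha Per-patient, per-class one-sided test level. A patient joins
#'   subgroup `Ar` when the one-sided p-value for residue class `r` is
#'   strictly below `alpha`. Default 0.05.
#' @param divisor Integer divisor defining the residue classes; 5 targets
#'   preference for weights ending in 0 or 5. Must be >= 2.
#' @param bootstrap_reps Default number of bootstrap replicates `B` for
#'   confidence intervals.
#' @param seed Optional integer seed recorded in reports and used by
#'   pipeline stages that randomise.
#' @param baseline_delta Alert threshold (pounds) for the baseline-deviation
#'   ("telehf") algorithm: a reading alerts when it deviates from the first
#'   recorded weight by at least this amount (default 3 lb).
#' @param daily_delta Alert threshold (pounds) for the day-to-day algorithm:
#'   a reading alerts when it differs from the previous calendar day's
#'   reading by strictly more than this amount (default 2 lb).
#' @param strict_baseline If `TRUE` the baseline algorithm requires a strict
#'   (`>`) rather than weak (`>=`) exceedance of `baseline_delta`.
#' @param test Per-class proportion test: `"score"` (one-sided normal
#'   approximation without continuity correction, the default) or `"exact"`
#'   (exact binomial tail).
#' @param suppression How the baseline algorithm interprets "consecutive
#'   days" when suppressing repeat alerts: `"calendar"` (default; only a
#'   reading on the immediately preceding calendar day can suppress) or
#'   `"submission"` (the previous submitted reading suppresses regardless
#'   of gaps).
#'
#' @return An object of class `edp_config` (a named list).
#' @examples
#' cfg <- edp_config(alpha = 0.05, divisor = 5)
#' cfg$alpha
#' @export
edp_config <- function(alpha = 0.05, divisor = 5L, bootstrap_reps = 1000L,
                       seed = NULL, baseline_delta = 3, daily_delta = 2,
                       strict_baseline = FALSE,
                       test = c("score", "exact"),
                       suppression = c("calendar", "submission")) {
  test <- match.arg(test)
  suppression <- match.arg(suppression)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  divisor <- as.integer(divisor)
  if (is.na(divisor) || divisor < 2L)
    stop("`divisor` must be an integer >= 2", call. = FALSE)
  if (baseline_delta <= 0 || daily_delta <= 0)
    stop("alert thresholds must be positive", call. = FALSE)
  bootstrap_reps <- as.integer(bootstrap_reps)
  if (is.na(bootstrap_reps) || bootstrap_reps < 1L)
    stop("`bootstrap_reps` must be a positive integer", call. = FALSE)
  structure(
    list(alpha = alpha, divisor = divisor, bootstrap_reps = bootstrap_reps,
         seed = seed, baseline_delta = baseline_delta,
         daily_delta = daily_delta, strict_baseline = strict_baseline,
         test = test, suppression = suppression),
    class = "edp_config"
  )
}

#' @export
print.edp_config <- function(x, ...) {
  cat("<edp_config>\n")
  cat(sprintf("  alpha: %g (one-sided, %s test)\n", x$alpha, x$test))
  cat(sprintf("  divisor: %d\n", x$divisor))
  cat(sprintf("  bootstrap replicates: %d\n", x$bootstrap_reps))
  cat(sprintf("  alert thresholds: baseline %g lb (%s), daily %g lb (strict)\n",
              x$baseline_delta, if (x$strict_baseline) ">" else ">=",
              x$daily_delta))
  invisible(x)
}
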