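#' Baseline-deviation ("Tele-HF") alert algorithm
#'
#' Reproduces the trial's alerting rule retrospectively. The baseline is
#' the first recorded weight, which cannot itself alert. A later reading
#' alerts when it deviates from baseline by at least `threshold` pounds in
#' either direction (`>` instead of `>=` with `strict = TRUE`), except
#' that an alert is suppressed when the immediately preceding calendar day
#' alerted and the weight is unchanged -- a repeat alert requires either a
#' day's gap or a changed weight that is still out of range.
#'
#' @param day Integer vector of reporting days (strictly increasing).
#' @param weight Numeric vector of reported weights, same length.
#' @param threshold Deviation threshold in pounds (default 3).
#' @param strict Require strict exceedance (default `FALSE`, i.e. `>=`).
#' @param suppression `"calendar"` (default): only the previous calendar
#'   day suppresses; `"submission"`: the previous submitted reading
#'   suppresses regardless of gaps.
#' @return An object of class `alert_series`: list with `algorithm`,
#'   `alert_days` (sorted subset of `day`) and `count`.
#' @examples
#' telehf_alerts(1:6, c(150, 154, 154, 151, 155, 155))$alert_days  # 2 and 5
#' @export
telehf_alerts <- function(day, weight, threshold = 3, strict = FALSE,
                          suppression = c("calendar", "submission")) {
  suppression <- match.arg(suppression)
  check_series(day, weight)
  n <- length(day)
  alert <- logical(n)
  base <- weight[1L]
  for (t in seq_len(n)[-1L]) {
    dev <- abs(weight[t] - base)
    hit <- if (strict) dev > threshold else dev >= threshold
    adjacent <- if (suppression == "calendar") day[t] - day[t - 1L] == 1L
    else TRUE
    suppressed <- adjacent && alert[t - 1L] && weight[t] == weight[t - 1L]
    alert[t] <- hit && !suppressed
  }
  new_alert_series("telehf", day[alert])
}

#' Day-to-day change alert algorithm
#'
#' Alerts when the reported weight changes by strictly more than
#' `threshold` pounds (default 2 lb) from one calendar day to the next.
#' Comparisons are only made between readings on consecutive calendar
#' days: a gap in reporting produces no alert, since the day-on-day change
#' is unobserved.
#'
#' @inheritParams telehf_alerts
#' @param threshold Change threshold in pounds (default 2; the rule is
#'   strict, `> threshold`).
#' @return An `alert_series` (see [telehf_alerts()]).
#' @examples
#' daydelta_alerts(1:4, c(150, 153, 153, 150))$alert_days  # 2 and 4
#' @export
daydelta_alerts <- function(day, weight, threshold = 2) {
  check_series(day, weight)
  n <- length(day)
  if (n < 2L) return(new_alert_series("daydelta", integer(0)))
  consec <- diff(day) == 1L
  jump <- abs(diff(weight)) > threshold
  new_alert_series("daydelta", day[-1L][consec & jump])
}

check_series <- function(day, weight) {
  if (length(day) == 0L) stop("empty series", call. = FALSE)
  if (length(day) != length(weight))
    stop("`day` and `weight` lengths differ", call. = FALSE)
  if (any(diff(day) <= 0))
    stop("`day` must be strictly increasing", call. = FALSE)
  invisible(TRUE)
}

new_alert_series <- function(algorithm, alert_days) {
  structure(list(algorithm = algorithm,
                 alert_days = as.integer(alert_days),
                 count = length(alert_days)),
            class = "alert_series")
}

#' @export
print.alert_series <- function(x, ...) {
  cat(sprintf("<alert_series> %s: %d alert(s) on day(s) %s\n",
              x$algorithm, x$count,
              if (x$count) paste(x$alert_days, collapse = ", ") else "-"))
  invisible(x)
}

#' Per-patient alert counts for a whole readings table
#'
#' @param readings Readings tibble (`patient_id`, `day`, `weight`).
#' @param algorithm `"telehf"` or `"daydelta"`.
#' @param config An [edp_config()] supplying thresholds and strictness.
#' @return A tibble with `patient_id` and `alerts` (integer count).
#' @export
alert_counts <- function(readings, algorithm = c("telehf", "daydelta"),
                         config = edp_config()) {
  algorithm <- match.arg(algorithm)
  sp <- split(readings[c("day", "weight")], readings$patient_id)
  counts <- vapply(sp, function(s) {
    s <- s[order(s$day), ]
    if (algorithm == "telehf")
      telehf_alerts(s$day, s$weight, config$baseline_delta,
                    config$strict_baseline, config$suppression)$count
    else daydelta_alerts(s$day, s$weight, config$daily_delta)$count
  }, integer(1))
  tibble::tibble(patient_id = names(sp), alerts = unname(counts))
}

#' EDP versus NEDP mean alert counts
#'
#' Treats each patient's alert count over the monitoring period as a
#' covariate and pushes it through the weighted-average estimators: the
#' EDP mean via [edp_mean()], the NEDP mean as the pooled `A1`-`A4` mean,
#' with percentile bootstrap intervals from the shared patient-level
#' bootstrap.
#'
#' @param counts Tibble from [alert_counts()].
#' @param assignments Output of [assign_subgroups()] for the same
#'   patients.
#' @param B Bootstrap replicates.
#' @param seed Optional seed.
#' @return A tibble (statistics `edp_mean_alerts`, `nedp_mean_alerts`)
#'   with point estimates and confidence limits.
#' @export
group_alert_summary <- function(counts, assignments, B = 1000L,
                                seed = NULL) {
  cov <- tibble::tibble(patient_id = counts$patient_id,
                        alerts = counts$alerts)
  bt <- edp_bootstrap(assignments, cov, B = B, seed = seed)
  bt[bt$statistic %in% c("edp_mean_alerts", "nedp_mean_alerts"), ]
}

#' Within-person variance of reported weights
#'
#' Sample variance (denominator `n - 1`) of each patient's reported
#' weights. Patients with a single reading have undefined variance and
#' are returned with `NA` (the per-subgroup mean in
#' [covariate_summaries()] then excludes them available-case).
#'
#' @param readings Readings tibble.
#' @return A tibble with `patient_id`, `n_readings`, `variance`.
#' @examples
#' r <- tibble::tibble(patient_id = "p", day = 0:1, weight = c(140, 145))
#' within_person_variance(r)$variance  # 12.5
#' @export
within_person_variance <- function(readings) {
  sp <- split(readings$weight, readings$patient_id)
  tibble::tibble(
    patient_id = names(sp),
    n_readings = unname(vapply(sp, length, integer(1))),
    variance = unname(vapply(sp, function(w)
      if (length(w) < 2L) NA_real_ else stats::var(w), numeric(1))))
}
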