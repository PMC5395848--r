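#' End-to-end analysis pipeline
#'
#' Runs every analysis stage on a readings table (and optional covariate
#' table): reading-level digit diagnostics, per-patient subgroup
#' assignment, the two-stage EDP estimator with bootstrap intervals, and
#' both alert algorithms with EDP/NEDP summaries. Deterministic for a
#' fixed `config$seed`.
#'
#' @param readings Readings tibble (see [read_weight_readings()]).
#' @param covariates Optional covariate tibble.
#' @param config An [edp_config()].
#' @param output_dir Optional directory; when given, writes
#'   `report.json` (via [write_report()]) and the per-patient
#'   `assignments.csv` there.
#' @param bootstrap Compute bootstrap intervals (default `TRUE`).
#' @return A list of class `edp_report` with components `digits`
#'   (distribution, uniformity test, excess estimate, trend, divisor
#'   table), `subgroups` (assignments and sizes), `estimate` (EDP/NEDP
#'   counts, characteristics, bootstrap), `alerts` (per-algorithm counts
#'   and group summaries), `quality` (flags: negative EDP count,
#'   non-estimable trend, excluded bootstrap replicates) and `config`.
#' @export
run_edp_pipeline <- function(readings, covariates = NULL,
                             config = edp_config(), output_dir = NULL,
                             bootstrap = TRUE) {
  dist <- remainder_distribution(readings, config$divisor)
  digits <- list(
    distribution = list(counts = as.list(dist$counts), total = dist$total,
                        divisor = dist$divisor),
    uniformity = uniformity_chisq(dist),
    excess = unclass(excess_multiples(dist)),
    trend = multiple_of_five_trend(readings, config$divisor),
    divisor_table = divisor_sensitivity(readings, alpha = config$alpha))

  ana <- edp_analysis(readings, covariates, config, bootstrap = bootstrap)

  alerts <- list()
  for (alg in c("telehf", "daydelta")) {
    cnt <- alert_counts(readings, alg, config)
    alerts[[alg]] <- list(
      counts = cnt,
      summary = if (bootstrap && nrow(ana$assignments) >= 2L)
        group_alert_summary(cnt, ana$assignments,
                            B = config$bootstrap_reps,
                            seed = config$seed))
  }

  quality <- list(
    negative_edp_count = ana$estimate$negative,
    trend_estimable = digits$trend$estimable,
    bootstrap_excluded = if (!is.null(ana$bootstrap))
      max(ana$bootstrap$n_excluded) else NA_integer_,
    seed = config$seed)

  report <- structure(
    list(digits = digits,
         subgroups = list(sizes = ana$table$sizes,
                          unassigned = ana$table$unassigned,
                          n_patients = ana$table$n_patients),
         estimate = list(edp_count = ana$estimate$edp_count,
                         edp_fraction = ana$estimate$edp_fraction,
                         nedp_count = ana$nedp_count,
                         characteristics = ana$characteristics,
                         bootstrap = ana$bootstrap),
         alerts = lapply(alerts, function(a)
           list(mean_alerts = mean(a$counts$alerts), summary = a$summary)),
         quality = quality, config = unclass(config)),
    class = "edp_report")
  attr(report, "assignments") <- ana$assignments
  attr(report, "alert_counts") <- lapply(alerts, `[[`, "counts")

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_report(report, file.path(output_dir, "report.json"))
    utils::write.csv(ana$assignments,
                     file.path(output_dir, "assignments.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.edp_report <- function(x, ...) {
  cat("<edp_report>\n")
  cat(sprintf("  readings: %d; multiples-of-divisor share %.1f%% (excess %.1f, %.1f%% of readings)\n",
              x$digits$excess$total, 100 * x$digits$excess$observed_fraction,
              x$digits$excess$excess, 100 * x$digits$excess$excess_fraction))
  cat(sprintf("  subgroup sizes: %s (unassigned %s)\n",
              paste(x$subgroups$sizes, collapse = ", "),
              x$subgroups$unassigned))
  cat(sprintf("  estimated EDP patients: %.1f (%.1f%%); NEDP: %.1f\n",
              x$estimate$edp_count, 100 * x$estimate$edp_fraction,
              x$estimate$nedp_count))
  for (alg in names(x$alerts))
    cat(sprintf("  mean alerts (%s): %.2f\n", alg,
                x$alerts[[alg]]$mean_alerts))
  invisible(x)
}
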