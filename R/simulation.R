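#' Closed-form probability that an EDP patient is assigned to A0
#'
#' Independent oracle for the limiting (iid-uniform-residue) regime under
#' the fixed-count rounding model. An EDP patient with `n_days` readings
#' rounds exactly `m = round(q * n_days)` of them (all landing in class
#' 0); the remaining `n_days - m` readings contribute class-0 counts as
#' `Binomial(n_days - m, p0)`. Assignment to `A0` occurs when the total
#' class-0 count reaches the rejection threshold `k*(n_days)` of the
#' per-patient proportion test, so the probability is
#' `P(Binom(n_days - m, p0) >= k* - m)` (1 when `k* <= m`).
#'
#' @param n_days Number of reporting days.
#' @param q Fraction of days rounded.
#' @param p0 Chance rate per class (default 0.2).
#' @param alpha Test level (default 0.05).
#' @param test Proportion test used for the threshold (see
#'   [rejection_threshold()]).
#' @return Probability in `[0, 1]`.
#' @examples
#' closed_form_assignment_prob(10, 0.3)   # ~0.423
#' closed_form_assignment_prob(40, 0.3)   # ~0.998
#' @export
closed_form_assignment_prob <- function(n_days, q, p0 = 0.2, alpha = 0.05,
                                        test = c("score", "exact")) {
  test <- match.arg(test)
  stopifnot(n_days >= 1, q >= 0, q <= 1)
  m <- round(q * n_days)
  ks <- rejection_threshold(n_days, p0 = p0, alpha = alpha, test = test)
  if (ks <= m) return(1)
  stats::pbinom(ks - m - 1, n_days - m, p0, lower.tail = FALSE)
}

#' Closed-form chance assignment probability for an NEDP patient
#'
#' Probability that a patient without end-digit preference, whose
#' residues are iid uniform, is assigned to any one given subgroup:
#' `P(Binom(n_days, p0) >= k*(n_days))`.
#'
#' @inheritParams closed_form_assignment_prob
#' @return Probability in `[0, 1]`.
#' @examples
#' closed_form_null_prob(162)  # ~0.059
#' @export
closed_form_null_prob <- function(n_days, p0 = 0.2, alpha = 0.05,
                                  test = c("score", "exact")) {
  test <- match.arg(test)
  ks <- rejection_threshold(n_days, p0 = p0, alpha = alpha, test = test)
  stats::pbinom(ks - 1, n_days, p0, lower.tail = FALSE)
}

#' Run one simulation scenario
#'
#' Generates a cohort under the given data-generating regime, assigns
#' subgroups with the per-patient proportion tests, and scores the
#' assignments against the ground-truth EDP labels. "A1-A4" membership
#' means membership in at least one of those subgroups; the NEDP share of
#' A1-A4 counts membership instances (a patient in two of A1-A4 counts
#' twice).
#'
#' @param edp_fraction Fraction of patients labelled EDP.
#' @param round_fraction `q`, fraction of days rounded.
#' @param sd_daily Daily-change SD in pounds, or `"limiting"`.
#' @param n_days Reporting days per patient.
#' @param n_patients Cohort size (default 10000).
#' @param seed Optional seed.
#' @param config An [edp_config()].
#' @return A one-row tibble: the scenario parameters plus `edp_a0`,
#'   `edp_a14`, `nedp_a0`, `nedp_a14` (percentages of EDP/NEDP patients
#'   assigned to `A0` / to any of `A1`-`A4`), `nedp_share_a14` (percentage
#'   of `A1`-`A4` membership instances that are NEDP), `equal_assignment_p`
#'   (chi-squared p-value for equal NEDP assignment across `A0`-`A4`) and,
#'   for limiting-mode scenarios, the closed-form oracle `edp_a0_closed`.
#' @export
run_scenario <- function(edp_fraction = 0.15, round_fraction = 0.3,
                         sd_daily = "limiting", n_days = 162L,
                         n_patients = 10000L, seed = NULL,
                         config = edp_config()) {
  cc <- cohort_config(n_patients, edp_fraction = edp_fraction,
                      round_fraction = round_fraction, sd_daily = sd_daily,
                      n_days = n_days, seed = seed)
  cohort <- generate_cohort(cc)
  asg <- assign_subgroups(cohort$readings, config)
  m <- membership_matrix(asg)
  is_edp <- cohort$truth$is_edp[match(rownames(m), cohort$truth$patient_id)]

  a0 <- m[, 1L]
  a14 <- rowSums(m[, -1L, drop = FALSE]) > 0
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_

  inst_nedp <- sum(m[!is_edp, -1L, drop = FALSE])
  inst_all <- sum(m[, -1L, drop = FALSE])
  nedp_share <- if (inst_all > 0) 100 * inst_nedp / inst_all else NA_real_

  nedp_class_counts <- colSums(m[!is_edp, , drop = FALSE])
  eq_p <- if (sum(nedp_class_counts) > 0)
    stats::chisq.test(nedp_class_counts)$p.value else NA_real_

  is_limiting <- identical(sd_daily, "limiting")
  closed <- if (is_limiting)
    100 * closed_form_assignment_prob(n_days, round_fraction,
                                      p0 = 1 / config$divisor,
                                      alpha = config$alpha,
                                      test = config$test)
  else NA_real_

  tibble::tibble(
    edp_fraction = edp_fraction, round_fraction = round_fraction,
    sd_daily = if (is_limiting) NA_real_ else sd_daily,
    limiting = is_limiting,
    n_days = as.integer(n_days), n_patients = as.integer(n_patients),
    edp_a0 = pct(a0[is_edp]), edp_a14 = pct(a14[is_edp]),
    nedp_a0 = pct(a0[!is_edp]), nedp_a14 = pct(a14[!is_edp]),
    nedp_share_a14 = nedp_share, equal_assignment_p = eq_p,
    edp_a0_closed = closed)
}

#' Run a full scenario grid
#'
#' Three pre-defined grids mirror the standard simulation layouts:
#' `"mix"` crosses EDP fractions \{15%, 30%, 60%\} with rounding
#' fractions \{30%, 50%, 70%\} in the limiting regime at 162 days;
#' `"volatility"` varies the daily-change SD
#' \{0, 0.05, 0.1, 0.5, 1, limiting\} at 15%/30%; `"compliance"` varies
#' the number of reporting days \{10, 20, 40, 60, 80, 162, 180\} in the
#' limiting regime at 15%/30%. Numeric ids 3, 4 and 5 are accepted as
#' aliases, in that order.
#'
#' @param grid `"mix"`, `"volatility"` or `"compliance"` (or 3, 4, 5).
#' @param n_patients Patients per scenario (default 10000).
#' @param seed Base seed; scenario `i` uses `seed + i`.
#' @param config An [edp_config()].
#' @return A tibble with one [run_scenario()] row per grid row.
#' @export
run_table <- function(grid, n_patients = 10000L, seed = NULL,
                      config = edp_config()) {
  if (is.numeric(grid))
    grid <- switch(as.character(grid), "3" = "mix", "4" = "volatility",
                   "5" = "compliance",
                   stop("unknown grid id: ", grid, call. = FALSE))
  grid <- match.arg(grid, c("mix", "volatility", "compliance"))
  rows <- switch(grid,
    mix = {
      g <- expand.grid(f = c(0.15, 0.30, 0.60), q = c(0.3, 0.5, 0.7))
      g <- g[order(g$f, g$q), ]
      lapply(seq_len(nrow(g)), function(i)
        list(f = g$f[i], q = g$q[i], sd = "limiting", nd = 162L))
    },
    volatility = lapply(list(0, 0.05, 0.1, 0.5, 1, "limiting"), function(s)
      list(f = 0.15, q = 0.3, sd = s, nd = 162L)),
    compliance = lapply(c(10L, 20L, 40L, 60L, 80L, 162L, 180L), function(n)
      list(f = 0.15, q = 0.3, sd = "limiting", nd = n)))
  res <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    run_scenario(edp_fraction = r$f, round_fraction = r$q, sd_daily = r$sd,
                 n_days = r$nd, n_patients = n_patients,
                 seed = if (is.null(seed)) NULL else seed + i,
                 config = config)
  })
  do.call(rbind, res)
}
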