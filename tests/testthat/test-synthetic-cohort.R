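test_that("true weight paths have the stated moments", {
  # sd 0: constant path at the start weight
  expect_equal(generate_true_weights(10, 0, start = 151.2), rep(151.2, 10))

  # limiting mode: residue frequencies uniform (law of large numbers)
  set.seed(11)
  w <- generate_true_weights(1e6, "limiting")
  freq <- tabulate(remainder_of(w) + 1L, 5) / 1e6
  expect_lt(max(abs(freq - 0.2)), 0.002)

  # random walk: day-to-day increment SD recovers sd_daily
  set.seed(12)
  d <- vapply(1:1e4, function(i) diff(generate_true_weights(2, 1, 170)),
              numeric(1))
  expect_equal(sd(d), 1, tolerance = 0.03)
  expect_equal(mean(d), 0, tolerance = 0.05)

  expect_error(generate_true_weights(5, -1), "non-negative")
})

test_that("reporting rounds the configured days to the nearest five", {
  # NEDP: integer part, no rounded days
  r <- apply_reporting(c(150.9, 151.4, 152.8), is_edp = FALSE, q = 0.5)
  expect_equal(r$reported, c(150, 151, 152))
  expect_length(r$rounded_days, 0L)

  # q = 1: every report is the nearest multiple of five
  r <- apply_reporting(rep(142.3, 6), is_edp = TRUE, q = 1)
  expect_equal(r$reported, rep(140, 6))

  # exact midpoints round up
  expect_equal(apply_reporting(142.5, TRUE, 1)$reported, 145)

  # fixed-count model: exactly round(q n) days in every realisation
  for (s in 1:25) {
    set.seed(s)
    r <- apply_reporting(runif(10, 120, 220), is_edp = TRUE, q = 0.3)
    expect_length(r$rounded_days, 3L)
  }

  expect_error(apply_reporting(1:3, TRUE, q = 1.5), "\\[0, 1\\]")
})

test_that("rounded reports are always multiples of five", {
  set.seed(21)
  for (sd in list(0, 0.5, "limiting")) {
    coh <- generate_cohort(cohort_config(40, edp_fraction = 0.5,
                                         round_fraction = 0.4,
                                         sd_daily = sd, n_days = 30))
    rd <- merge(coh$rounding_days, coh$readings)
    expect_true(all(remainder_of(rd$weight) == 0L))
    # NEDP patients have an empty rounding set
    nedp <- coh$truth$patient_id[!coh$truth$is_edp]
    expect_equal(coh$truth$n_rounded_days[!coh$truth$is_edp],
                 rep(0L, length(nedp)))
    expect_false(any(coh$rounding_days$patient_id %in% nedp))
  }
})

test_that("cohort generation labels the exact EDP count and is reproducible", {
  cfg <- cohort_config(2000, edp_fraction = 0.15, n_days = 3L, seed = 7)
  coh <- generate_cohort(cfg)
  expect_equal(sum(coh$truth$is_edp), 300L)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$readings, coh2$readings)
  expect_identical(coh$truth, coh2$truth)

  # edp_fraction 0 in the limiting regime: residues near-uniform
  coh0 <- generate_cohort(cohort_config(500, edp_fraction = 0,
                                        sd_daily = "limiting",
                                        n_days = 200L, seed = 8))
  freq <- remainder_distribution(coh0$readings)$counts / 1e5
  expect_lt(max(abs(freq - 0.2)), 0.01)
})

test_that("multiples-of-five share matches the closed-form mixture", {
  # with f labelled EDP rounding m/n of days, the expected share of
  # class-0 reports is f (q + (1-q)/5) + (1-f)/5
  f <- 0.3; q <- 0.5; n_days <- 100L
  coh <- generate_cohort(cohort_config(500, edp_fraction = f,
                                       round_fraction = q,
                                       sd_daily = "limiting",
                                       n_days = n_days, seed = 9))
  share <- mean(remainder_of(coh$readings$weight) == 0L)
  expected <- f * (q + (1 - q) * 0.2) + (1 - f) * 0.2
  expect_equal(share, expected, tolerance = 0.02)
})

test_that("null cohorts reject uniformity at the nominal rate", {
  set.seed(31)
  rejections <- vapply(1:200, function(i) {
    coh <- generate_cohort(cohort_config(40, edp_fraction = 0,
                                         sd_daily = "limiting",
                                         n_days = 25L))
    uniformity_chisq(remainder_distribution(coh$readings))$p_value < 0.05
  }, logical(1))
  # E[rate] = 0.05, binomial SE ~ 0.015 over 200 draws
  expect_gt(mean(rejections), 0.003)
  expect_lt(mean(rejections), 0.11)
})

test_that("covariates differ by group as configured", {
  coh <- generate_cohort(cohort_config(
    3000, edp_fraction = 0.5, n_days = 2L, seed = 13,
    covariate_effects = example_covariate_effects()))
  cv <- merge(coh$covariates, coh$truth)
  m_edp <- tapply(cv$age, cv$is_edp, mean)
  expect_lt(abs(m_edp[["TRUE"]] - 60), 1.5)
  expect_lt(abs(m_edp[["FALSE"]] - 64), 1.5)
  p_male <- tapply(cv$male, cv$is_edp, mean)
  expect_lt(abs(p_male[["TRUE"]] - 0.69), 0.05)
  expect_lt(abs(p_male[["FALSE"]] - 0.55), 0.05)
})

test_that("cohorts round-trip through the CSV writers", {
  coh <- generate_cohort(cohort_config(
    15, n_days = 8L, seed = 5, covariate_effects = example_covariate_effects()))
  dir <- tempfile()
  write_cohort(coh, dir)
  back <- read_weight_readings(file.path(dir, "readings.csv"))
  expect_equal(as.data.frame(back), as.data.frame(coh$readings))
  truth <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(as.logical(truth$is_edp), coh$truth$is_edp)
  expect_equal(truth$n_rounded_days, coh$truth$n_rounded_days)
})
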