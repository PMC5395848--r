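test_that("baseline algorithm matches the hand-traced rule", {
  # baseline 150; deviations 0,4,4,1,5,5 -> alert on days 2 and 5 only
  # (days 3 and 6 are suppressed: previous day alerted, weight unchanged)
  a <- telehf_alerts(1:6, c(150, 154, 154, 151, 155, 155))
  expect_equal(a$alert_days, c(2L, 5L))
  expect_equal(a$count, 2L)

  # changed weight still out of range alerts on consecutive days
  a <- telehf_alerts(1:3, c(150, 154, 156))
  expect_equal(a$alert_days, c(2L, 3L))

  # constant series, and the baseline day itself, never alert
  expect_equal(telehf_alerts(0:9, rep(180, 10))$count, 0L)
  expect_equal(telehf_alerts(0L, 200)$count, 0L)

  # after a missed day an unchanged out-of-range weight alerts again
  a <- telehf_alerts(c(1, 2, 4), c(150, 154, 154))
  expect_equal(a$alert_days, c(2L, 4L))
  # ... but not under consecutive-submission suppression
  a2 <- telehf_alerts(c(1, 2, 4), c(150, 154, 154),
                      suppression = "submission")
  expect_equal(a2$alert_days, 2L)
})

test_that("day-to-day algorithm alerts on >2 lb between consecutive days", {
  a <- daydelta_alerts(1:4, c(150, 153, 153, 150))
  expect_equal(a$alert_days, c(2L, 4L))
  expect_equal(daydelta_alerts(0:5, rep(170, 6))$count, 0L)
  # a reporting gap produces no alert even for a large change
  expect_equal(daydelta_alerts(c(0L, 7L), c(150, 155))$count, 0L)
  # single reading: zero alerts
  expect_equal(daydelta_alerts(3L, 150)$count, 0L)
})

test_that("alert invariants hold on random series", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    day <- sort(sample(0:60, n))
    w <- round(150 + cumsum(rnorm(n, 0, 2)))
    strict <- telehf_alerts(day, w, strict = TRUE)$alert_days
    weak <- telehf_alerts(day, w, strict = FALSE)$alert_days
    expect_true(all(strict %in% weak))
    expect_true(all(weak %in% day))
    # for integer weights, "> 2" equals ">= 3" day-to-day
    consec <- diff(day) == 1L
    ge3 <- day[-1L][consec & abs(diff(w)) >= 3]
    expect_equal(daydelta_alerts(day, w)$alert_days, ge3)
  }
  # prepending baseline-identical readings does not change alerts
  a0 <- telehf_alerts(5:8, c(150, 155, 151, 147))
  a1 <- telehf_alerts(1:8, c(150, 150, 150, 150, 150, 155, 151, 147))
  expect_equal(a0$count, a1$count)
})

test_that("within-person variance and per-patient counts are correct", {
  expect_equal(within_person_variance(one_series(rep(140, 5)))$variance, 0)
  expect_equal(within_person_variance(one_series(c(140, 145)))$variance, 12.5)
  expect_true(is.na(within_person_variance(one_series(140))$variance))

  r <- rbind(one_series(c(150, 154, 154, 151, 155, 155), id = "a", days = 1:6),
             one_series(c(150, 153, 153, 150), id = "b", days = 1:4))
  ct <- alert_counts(r, "telehf")
  expect_equal(ct$alerts[ct$patient_id == "a"], 2L)
  cd <- alert_counts(r, "daydelta")
  expect_equal(cd$alerts[cd$patient_id == "b"], 2L)
})

test_that("group summaries push alert counts through the estimators", {
  # identical alert counts: EDP mean = NEDP mean = the common count
  # (A0 oversized so the estimated EDP count is positive)
  r <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      pure_class_series(paste0("p0", letters[i]), 0L, n = 40L))),
    do.call(rbind, lapply(1:4, function(cl)
      pure_class_series(paste0("p", cl), cl, n = 40L))))
  asg <- assign_subgroups(r)
  counts <- tibble::tibble(patient_id = sort(unique(r$patient_id)),
                           alerts = 2L)
  gs <- group_alert_summary(counts, asg, B = 50, seed = 3)
  expect_equal(gs$estimate[gs$statistic == "edp_mean_alerts"], 2)
  expect_equal(gs$estimate[gs$statistic == "nedp_mean_alerts"], 2)

  # EDP rounding inflates volatility: EDP mean alerts >= NEDP mean,
  # and subgroup A0's mean within-person variance exceeds a clean cohort's
  coh <- generate_cohort(cohort_config(400, edp_fraction = 0.3,
                                       round_fraction = 0.5, sd_daily = 0.5,
                                       n_days = 60L, seed = 32))
  asg <- assign_subgroups(coh$readings)
  cnt <- alert_counts(coh$readings, "daydelta")
  gs <- group_alert_summary(cnt, asg, B = 100, seed = 4)
  expect_gte(gs$estimate[gs$statistic == "edp_mean_alerts"],
             gs$estimate[gs$statistic == "nedp_mean_alerts"])

  v <- within_person_variance(coh$readings)
  cs <- covariate_summaries(asg, v[c("patient_id", "variance")])
  coh0 <- generate_cohort(cohort_config(400, edp_fraction = 0,
                                        sd_daily = 0.5, n_days = 60L,
                                        seed = 33))
  v0 <- mean(within_person_variance(coh0$readings)$variance)
  expect_gt(cs$mean[cs$subgroup == "A0"], v0)
})
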