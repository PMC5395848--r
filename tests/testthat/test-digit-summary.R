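test_that("residue classes use the integer part of the weight", {
  expect_equal(remainder_of(145), 0L)
  expect_equal(remainder_of(142), 2L)
  expect_equal(remainder_of(169.4), 4L)
  expect_equal(remainder_of(c(140, 141, 142, 143, 144)), 0:4)
  expect_error(remainder_of(145, divisor = 1), ">= 2")
  expect_error(remainder_of(-3), "positive")
})

test_that("remainder distributions tabulate correctly", {
  d <- remainder_distribution(c(140, 145, 150))
  expect_equal(unname(d$counts), c(3L, 0L, 0L, 0L, 0L))
  d <- remainder_distribution(c(140, 141, 142, 143, 144))
  expect_equal(unname(d$counts), rep(1L, 5))
  expect_equal(d$total, 5L)
  expect_error(remainder_distribution(numeric(0)), "no readings")
})

test_that("uniformity statistic matches a brute-force Pearson sum", {
  # hand computation: counts (40,10,10,10,10), expected 16 per class
  u <- uniformity_chisq(as_remainder_distribution(c(40, 10, 10, 10, 10)))
  expect_equal(u$statistic, (24^2 + 4 * 6^2) / 16)  # = 45
  expect_equal(u$df, 4)

  # equal counts: statistic exactly 0, p = 1
  u0 <- uniformity_chisq(as_remainder_distribution(rep(12, 5)))
  expect_equal(u0$statistic, 0)
  expect_equal(u0$p_value, 1)

  # oracle equivalence on random small tables
  set.seed(14)
  for (i in 1:20) {
    counts <- rmultinom(1, sample(50:500, 1), rep(0.2, 5))[, 1]
    u <- uniformity_chisq(as_remainder_distribution(counts))
    e <- sum(counts) / 5
    expect_equal(u$statistic, sum((counts - e)^2 / e), tolerance = 1e-12)
    expect_gte(u$statistic, 0)
    expect_equal(u$p_value, pchisq(u$statistic, 4, lower.tail = FALSE))
  }
})

test_that("excess estimate reproduces the trial-scale arithmetic", {
  # split of classes 1-4 is irrelevant to the class-0 excess
  d <- as_remainder_distribution(c(44346, 17000, 17500, 18000, 18021))
  ex <- excess_multiples(d)
  expect_equal(ex$total, 114867L)
  expect_equal(ex$expected, 114867 / 5)        # ~22973
  expect_equal(ex$excess, 44346 - 114867 / 5)  # ~21373
  expect_equal(round(100 * ex$excess_fraction, 1), 18.6)
  expect_equal(round(100 * ex$observed_fraction, 1), 38.6)
  expect_false(ex$negative)

  # observed exactly at chance -> zero excess
  ex0 <- excess_multiples(as_remainder_distribution(rep(20, 5)))
  expect_equal(ex0$excess, 0)

  # deficit reported as-is with a flag, never clipped
  exn <- excess_multiples(as_remainder_distribution(c(10, 30, 20, 20, 20)))
  expect_equal(exn$excess, -10)
  expect_true(exn$negative)
})

test_that("excess fraction equals the share identity (property)", {
  set.seed(15)
  for (d in c(2L, 3L, 5L, 7L)) {
    counts <- rmultinom(1, 1000, runif(d, 0.5, 2))[, 1] + 1L
    ex <- excess_multiples(as_remainder_distribution(counts))
    expect_equal(ex$excess_fraction,
                 ex$observed / ex$total - 1 / d, tolerance = 1e-12)
    expect_equal(ex$excess_fraction * ex$total, ex$excess,
                 tolerance = 1e-9)
  }
})

test_that("trend regression recovers a known per-day odds ratio", {
  set.seed(16)
  n <- 1e5
  day <- sample(0:180, n, replace = TRUE)
  b <- log(1.002)
  p <- plogis(qlogis(0.25) + b * day)
  y <- rbinom(n, 1, p)
  # encode outcome in the weights: class 0 vs class 2
  readings <- tibble::tibble(patient_id = "x", day = day,
                             weight = ifelse(y == 1, 150, 152))
  tr <- multiple_of_five_trend(readings)
  expect_true(tr$estimable)
  expect_gt(tr$odds_ratio, 1)
  expect_true(tr$ci_lower <= 1.002 && 1.002 <= tr$ci_upper)
  expect_true(tr$ci_lower <= tr$odds_ratio & tr$odds_ratio <= tr$ci_upper)

  # implementation matches an independent reference fit
  ref <- glm(y ~ day, family = binomial())
  expect_equal(tr$log_or, unname(coef(ref)["day"]), tolerance = 1e-6)
})

test_that("trend CI covers a null slope at the nominal rate", {
  set.seed(17)
  covered <- vapply(1:200, function(i) {
    day <- sample(0:180, 1500, replace = TRUE)
    y <- rbinom(1500, 1, 0.2)
    r <- tibble::tibble(patient_id = "x", day = day,
                        weight = ifelse(y == 1, 150, 152))
    tr <- multiple_of_five_trend(r)
    tr$ci_lower <= 1 && 1 <= tr$ci_upper
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("degenerate outcomes are flagged non-estimable, and permuting days kills a trend", {
  tr <- multiple_of_five_trend(one_series(rep(150, 50)))
  expect_false(tr$estimable)
  expect_true(is.na(tr$odds_ratio))

  set.seed(18)
  day <- sample(0:180, 5000, replace = TRUE)
  y <- rbinom(5000, 1, plogis(-2 + 0.02 * day))
  r <- tibble::tibble(patient_id = "x", day = day,
                      weight = ifelse(y == 1, 150, 152))
  expect_lt(multiple_of_five_trend(r)$p_value, 1e-6)
  r$day <- sample(r$day)
  tr_perm <- multiple_of_five_trend(r)
  expect_gt(tr_perm$p_value, 1e-4)
  expect_equal(tr_perm$odds_ratio, 1, tolerance = 0.02)
})

test_that("divisor specificity flags 5 and clears other primes", {
  coh <- generate_cohort(cohort_config(300, edp_fraction = 0.3,
                                       round_fraction = 0.7,
                                       sd_daily = "limiting",
                                       n_days = 50L, seed = 19))
  tab <- divisor_sensitivity(coh$readings, divisors = c(3L, 5L, 7L))
  expect_true(tab$significant[tab$divisor == 5L])
  expect_gt(tab$excess_fraction[tab$divisor == 5L], 0.1)
  # other primes: class-0 share within 3 Monte-Carlo SE of chance
  for (d in c(3L, 7L)) {
    row <- tab[tab$divisor == d, ]
    se <- sqrt((1 / d) * (1 - 1 / d) / row$total)
    expect_lt(abs(row$observed / row$total - 1 / d), 3 * se)
  }
  expect_error(divisor_sensitivity(coh$readings, divisors = 1L), ">= 2")
  expect_equal(nrow(divisor_sensitivity(coh$readings, divisors = integer(0))),
               0L)
})
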