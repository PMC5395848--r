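#' Residue class of a reported weight
#'
#' The residue class is computed on the integer part of the reported
#' weight: `floor(weight) %% divisor`. With the default divisor 5 the
#' classes 0-4 correspond to final digits \{0,5\}, \{1,6\}, \{2,7\},
#' \{3,8\} and \{4,9\}.
#'
#' @param weight Positive numeric vector of reported weights (pounds).
#' @param divisor Integer divisor >= 2 (default 5).
#' @return Integer vector of residue classes in `0:(divisor - 1)`.
#' @examples
#' remainder_of(c(145, 142, 169.4))
#' @export
remainder_of <- function(weight, divisor = 5L) {
  divisor <- as.integer(divisor)
  if (is.na(divisor) || divisor < 2L)
    stop("`divisor` must be an integer >= 2", call. = FALSE)
  if (any(weight <= 0, na.rm = TRUE))
    stop("weights must be positive", call. = FALSE)
  as.integer(floor(weight)) %% divisor
}

#' Distribution of residue classes
#'
#' Tabulates readings by residue class. Under accurate reporting all
#' classes are equally likely, so departures from uniformity -- in
#' particular an excess in class 0 -- signal end-digit preference.
#'
#' @param weights Numeric vector of reported weights, or a readings tibble
#'   with a `weight` column.
#' @param divisor Integer divisor >= 2 (default 5).
#' @return An object of class `remainder_distribution`: a list with
#'   `counts` (named integer vector over classes `0:(divisor-1)`), `total`
#'   and `divisor`.
#' @examples
#' remainder_distribution(c(140, 141, 142, 143, 144))
#' @export
remainder_distribution <- function(weights, divisor = 5L) {
  if (is.data.frame(weights)) weights <- weights$weight
  if (length(weights) == 0L)
    stop("no readings supplied", call. = FALSE)
  r <- remainder_of(weights, divisor)
  counts <- tabulate(r + 1L, nbins = as.integer(divisor))
  names(counts) <- as.character(seq_len(divisor) - 1L)
  structure(list(counts = counts, total = sum(counts),
                 divisor = as.integer(divisor)),
            class = "remainder_distribution")
}

#' Build a remainder distribution from published class counts
#'
#' Constructs the same object [remainder_distribution()] computes from raw
#' readings, but starting from a vector of per-class counts -- e.g. totals
#' printed in a report, where the raw readings are unavailable.
#'
#' @param counts Non-negative integer vector of counts per residue class,
#'   ordered from class 0; its length sets the divisor.
#' @return A `remainder_distribution`.
#' @examples
#' as_remainder_distribution(c(40, 10, 10, 10, 10))
#' @export
as_remainder_distribution <- function(counts) {
  if (length(counts) < 2L)
    stop("need counts for at least two residue classes", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  counts <- as.integer(counts)
  names(counts) <- as.character(seq_along(counts) - 1L)
  structure(list(counts = counts, total = sum(counts),
                 divisor = length(counts)),
            class = "remainder_distribution")
}

#' @export
print.remainder_distribution <- function(x, ...) {
  cat(sprintf("<remainder_distribution> divisor %d, %d readings\n",
              x$divisor, x$total))
  print(rbind(count = x$counts,
              share = round(x$counts / x$total, 4)))
  invisible(x)
}

#' @export
plot.remainder_distribution <- function(x, ...) {
  graphics::barplot(x$counts, xlab = sprintf("Remainder (mod %d)", x$divisor),
                    ylab = "Number of readings", ...)
  graphics::abline(h = x$total / x$divisor, lty = 2)
  invisible(x)
}

#' Chi-squared test of residue-class uniformity
#'
#' Pearson goodness-of-fit test of the observed residue counts against the
#' uniform distribution over classes (expected count `total/divisor` per
#' class), with `divisor - 1` degrees of freedom.
#'
#' @param dist A `remainder_distribution`.
#' @return A list with `statistic`, `df` and `p_value`.
#' @examples
#' d <- remainder_distribution(c(140, 145, 150, 141, 152))
#' uniformity_chisq(d)
#' @export
uniformity_chisq <- function(dist) {
  stopifnot(inherits(dist, "remainder_distribution"))
  if (dist$total <= 0L) stop("empty distribution", call. = FALSE)
  ht <- stats::chisq.test(dist$counts)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Excess readings in residue class 0
#'
#' Estimates the number of readings affected by end-digit preference as
#' the observed count in residue class 0 minus the count expected by
#' chance (`total/divisor`). A negative excess is reported as-is with
#' `negative = TRUE`, never clipped.
#'
#' @param dist A `remainder_distribution`.
#' @return An object of class `excess_estimate`: `total`, `observed`,
#'   `expected`, `excess`, `excess_fraction` (excess / total),
#'   `observed_fraction` and `negative` flag. Expected counts are kept at
#'   full precision.
#' @examples
#' # class-0 count and total mirroring a trial-scale summary
#' d <- as_remainder_distribution(c(44346, 17000, 17500, 18000, 18021))
#' excess_multiples(d)
#' @export
excess_multiples <- function(dist) {
  stopifnot(inherits(dist, "remainder_distribution"))
  if (dist$total <= 0L) stop("empty distribution", call. = FALSE)
  observed <- unname(dist$counts[1L])
  expected <- dist$total / dist$divisor
  excess <- observed - expected
  structure(
    list(total = dist$total, observed = observed, expected = expected,
         excess = excess, excess_fraction = excess / dist$total,
         observed_fraction = observed / dist$total,
         negative = excess < 0),
    class = "excess_estimate"
  )
}

#' @export
print.excess_estimate <- function(x, ...) {
  cat(sprintf("<excess_estimate> %d of %d readings in class 0 (%.1f%%)\n",
              x$observed, x$total, 100 * x$observed_fraction))
  cat(sprintf("  expected by chance %.1f; excess %.1f (%.1f%% of readings)%s\n",
              x$expected, x$excess, 100 * x$excess_fraction,
              if (x$negative) " [NEGATIVE]" else ""))
  invisible(x)
}

#' Time trend in the probability of reporting a multiple of five
#'
#' Logistic regression at the reading level: the outcome is whether the
#' reported weight falls in residue class 0, the single covariate is the
#' number of days since enrolment. The reported odds ratio is per
#' additional day, with a Wald confidence interval on the log-odds scale.
#' One reading contributes one Bernoulli observation (no within-patient
#' clustering correction by default, matching a reading-level analysis);
#' set `cluster = TRUE` for a cluster-robust variance by patient.
#'
#' @param readings Tibble with `day`, `weight` and (if `cluster = TRUE`)
#'   `patient_id` columns.
#' @param divisor Integer divisor >= 2 (default 5).
#' @param conf Confidence level (default 0.95).
#' @param cluster Use a cluster-robust (by patient) variance estimate;
#'   requires the sandwich package.
#' @return A list with `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`,
#'   `log_or`, `se`, `n` and `estimable`. A constant outcome (all readings
#'   multiples of five, or none) is flagged `estimable = FALSE` with `NA`
#'   estimates rather than an error.
#' @export
multiple_of_five_trend <- function(readings, divisor = 5L, conf = 0.95,
                                   cluster = FALSE) {
  stopifnot(all(c("day", "weight") %in% names(readings)))
  y <- as.integer(remainder_of(readings$weight, divisor) == 0L)
  n <- length(y)
  out <- list(odds_ratio = NA_real_, ci_lower = NA_real_,
              ci_upper = NA_real_, p_value = NA_real_,
              log_or = NA_real_, se = NA_real_, n = n, estimable = FALSE)
  if (length(unique(y)) < 2L || length(unique(readings$day)) < 2L)
    return(out)
  fit <- stats::glm(y ~ day, family = stats::binomial(),
                    data = data.frame(y = y, day = readings$day))
  b <- stats::coef(fit)[["day"]]
  if (cluster) {
    if (!requireNamespace("sandwich", quietly = TRUE))
      stop("cluster-robust variance requires the sandwich package",
           call. = FALSE)
    v <- sandwich::vcovCL(fit, cluster = readings$patient_id)["day", "day"]
  } else {
    v <- stats::vcov(fit)["day", "day"]
  }
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out$log_or <- b
  out$se <- se
  out$odds_ratio <- exp(b)
  out$ci_lower <- exp(b - z * se)
  out$ci_upper <- exp(b + z * se)
  out$p_value <- 2 * stats::pnorm(abs(b / se), lower.tail = FALSE)
  out$estimable <- TRUE
  out
}

#' Specificity check across divisors
#'
#' Repeats the remainder analysis for a set of divisors (typically small
#' primes). Genuine preference for multiples of five should show a
#' significant class-0 excess for divisor 5 but not for other primes.
#' Divisor 2 inherits part of the signal (multiples of 10 are even), so
#' primes other than 5 are the cleanest negative controls.
#'
#' @param readings Readings tibble (or numeric weight vector).
#' @param divisors Integer vector of divisors >= 2. An empty vector
#'   returns an empty table.
#' @param alpha Significance level for flagging an excess (default 0.05).
#' @return A tibble with one row per divisor: class-0 `observed`,
#'   `expected`, `excess`, `excess_fraction`, chi-squared `uniformity_p`,
#'   one-sided `excess_p` (score test of the class-0 share against
#'   `1/divisor`) and the `significant` flag (`excess_p < alpha`).
#' @export
divisor_sensitivity <- function(readings, divisors = c(2L, 3L, 5L, 7L),
                                alpha = 0.05) {
  if (any(divisors < 2L))
    stop("all divisors must be >= 2", call. = FALSE)
  rows <- lapply(as.integer(divisors), function(d) {
    dist <- remainder_distribution(readings, d)
    ex <- excess_multiples(dist)
    u <- uniformity_chisq(dist)
    p_ex <- class_proportion_test(ex$observed, ex$total, p0 = 1 / d)
    tibble::tibble(divisor = d, total = ex$total, observed = ex$observed,
                   expected = ex$expected, excess = ex$excess,
                   excess_fraction = ex$excess_fraction,
                   uniformity_p = u$p_value, excess_p = p_ex,
                   significant = p_ex < alpha)
  })
  if (length(rows) == 0L)
    return(tibble::tibble(divisor = integer(), total = integer(),
                          observed = integer(), expected = numeric(),
                          excess = numeric(), excess_fraction = numeric(),
                          uniformity_p = numeric(), excess_p = numeric(),
                          significant = logical()))
  do.call(rbind, rows)
}
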