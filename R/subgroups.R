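#' One-sided binomial proportion test for a residue class
#'
#' Tests whether a patient's share of readings in one residue class exceeds
#' the chance rate `p0` (1/divisor, 0.2 for divisor 5). The default is the
#' one-sided score test without continuity correction:
#' `z = (k/n - p0) / sqrt(p0 (1 - p0) / n)`, with p-value the upper normal
#' tail. An exact binomial tail `P(X >= k)` is available via
#' `test = "exact"`; it is more conservative (larger rejection thresholds
#' at small n).
#'
#' @param k Number of readings in the class (vectorised; may be a matrix
#'   with one row per patient and one column per class).
#' @param n Total readings per patient (recycled along rows for matrix `k`).
#' @param p0 Null proportion (default 0.2).
#' @param test `"score"` (default) or `"exact"`.
#' @return One-sided p-values with the shape of `k`.
#' @examples
#' class_proportion_test(8, 20)   # ~0.0127
#' class_proportion_test(4, 20)   # exactly 0.5: null proportion attained
#' @export
class_proportion_test <- function(k, n, p0 = 0.2, test = c("score", "exact")) {
  test <- match.arg(test)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("`p0` must be in (0, 1)", call. = FALSE)
  if (test == "score") {
    z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
    p <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  }
  if (is.matrix(k)) p <- matrix(p, nrow = nrow(k), dimnames = dimnames(k))
  p
}

#' Smallest rejected class count for a given number of readings
#'
#' Returns `k*(n) = min{k : p(k, n) < alpha}`, the smallest class count
#' that triggers subgroup membership for a patient with `n` readings.
#' Decisions are monotone in `k`, so membership is equivalent to
#' `k >= k*(n)`. Returns `n + 1` when no count rejects.
#'
#' @inheritParams class_proportion_test
#' @param n Number of readings (scalar).
#' @param alpha One-sided test level (default 0.05).
#' @return Integer threshold.
#' @examples
#' rejection_threshold(10)  # 5
#' rejection_threshold(20)  # 7
#' rejection_threshold(40)  # 13
#' @export
rejection_threshold <- function(n, p0 = 0.2, alpha = 0.05,
                                test = c("score", "exact")) {
  test <- match.arg(test)
  stopifnot(length(n) == 1L, n >= 1)
  k <- 0:n
  p <- class_proportion_test(k, n, p0 = p0, test = test)
  hit <- which(p < alpha)
  if (length(hit) == 0L) as.integer(n + 1L) else as.integer(k[hit[1L]])
}

#' Assign patients to residue-class subgroups
#'
#' For each patient, the share of readings in every residue class is tested
#' against the chance rate `1/divisor` with a one-sided proportion test at
#' level `alpha`. A patient whose class-`r` p-value is strictly below
#' `alpha` joins subgroup `Ar`. Membership is not exclusive: a patient can
#' belong to several subgroups (or none). Subgroup `A0` is the candidate
#' superset of patients with end-digit preference; `A1`-`A4` calibrate the
#' chance rate of assignment. No minimum-readings filter is applied:
#' patients with few readings simply rarely reject.
#'
#' @param readings Readings tibble with `patient_id`, `day`, `weight`.
#' @param config An [edp_config()].
#' @return A tibble with one row per patient: `patient_id`, `n_readings`,
#'   class counts `k0`..`k4`, one-sided p-values `pval0`..`pval4`, logical
#'   membership columns `A0`..`A4` and a comma-separated `memberships`
#'   string. (For a general divisor `d` the columns run `A0`..`A(d-1)`.)
#' @examples
#' r <- tibble::tibble(patient_id = "p1", day = 0:29,
#'                     weight = rep(150, 30))
#' assign_subgroups(r)$memberships  # "A0"
#' @export
assign_subgroups <- function(readings, config = edp_config()) {
  stopifnot(all(c("patient_id", "weight") %in% names(readings)))
  if (nrow(readings) == 0L) stop("no readings supplied", call. = FALSE)
  d <- config$divisor
  res <- remainder_of(readings$weight, d)
  pid <- factor(readings$patient_id)
  k <- table(pid, factor(res, levels = 0:(d - 1L)))
  k <- matrix(as.integer(k), nrow = nlevels(pid),
              dimnames = list(levels(pid), 0:(d - 1L)))
  n <- rowSums(k)
  p <- class_proportion_test(k, n, p0 = 1 / d, test = config$test)
  member <- p < config$alpha
  classes <- paste0("A", 0:(d - 1L))
  out <- tibble::tibble(patient_id = rownames(k), n_readings = as.integer(n))
  for (j in seq_len(d)) out[[paste0("k", j - 1L)]] <- k[, j]
  for (j in seq_len(d)) out[[paste0("pval", j - 1L)]] <- p[, j]
  for (j in seq_len(d)) out[[classes[j]]] <- member[, j]
  out$memberships <- unname(apply(member, 1L,
                                  function(m) paste(classes[m], collapse = ",")))
  out
}

# logical membership matrix (patients x classes) from an assignments tibble
membership_matrix <- function(assignments) {
  cols <- grep("^A[0-9]+$", names(assignments), value = TRUE)
  cols <- cols[order(as.integer(sub("^A", "", cols)))]
  m <- as.matrix(assignments[cols])
  rownames(m) <- assignments$patient_id
  m
}

#' Subgroup membership counts
#'
#' Counts members per subgroup. A patient belonging to several subgroups
#' increments every one of them; `unassigned` counts patients in none.
#'
#' @param assignments Output of [assign_subgroups()].
#' @return A `subgroup_table`: list with `sizes` (named vector over
#'   `A0`..), `unassigned`, `n_patients`.
#' @export
subgroup_sizes <- function(assignments) {
  if (nrow(assignments) == 0L) stop("no patients supplied", call. = FALSE)
  m <- membership_matrix(assignments)
  subgroup_table(sizes = colSums(m),
                 unassigned = sum(rowSums(m) == 0L),
                 n_patients = nrow(m))
}

#' Construct a subgroup table directly
#'
#' Builds the per-subgroup size table used by the subtraction estimator,
#' either from [subgroup_sizes()] or directly from published membership
#' counts.
#'
#' @param sizes Numeric vector of subgroup sizes, ordered `A0`, `A1`, ...;
#'   names are added if absent.
#' @param unassigned Number of patients in no subgroup (optional).
#' @param n_patients Total patients assigned-or-not (optional).
#' @return An object of class `subgroup_table`.
#' @examples
#' subgroup_table(c(212, 96, 107, 130, 95))
#' @export
subgroup_table <- function(sizes, unassigned = NA_integer_,
                           n_patients = NA_integer_) {
  if (length(sizes) < 2L) stop("need at least two subgroups", call. = FALSE)
  if (any(sizes < 0)) stop("subgroup sizes must be non-negative", call. = FALSE)
  if (is.null(names(sizes)) || !all(nzchar(names(sizes))))
    names(sizes) <- paste0("A", seq_along(sizes) - 1L)
  structure(list(sizes = sizes, unassigned = unassigned,
                 n_patients = n_patients),
            class = "subgroup_table")
}

#' @export
print.subgroup_table <- function(x, ...) {
  cat("<subgroup_table>\n")
  print(x$sizes)
  if (!is.na(x$unassigned))
    cat(sprintf("  unassigned: %d of %d patients\n",
                x$unassigned, x$n_patients))
  invisible(x)
}

#' Per-subgroup covariate summaries
#'
#' Summarises each covariate within each subgroup: the available-case mean
#' over members (for a 0/1 covariate this is the member proportion).
#' Missing covariate values are excluded pairwise, covariate by covariate,
#' so each cell carries its own denominator `n_available`.
#'
#' @param assignments Output of [assign_subgroups()].
#' @param covariates Tibble with `patient_id` plus numeric covariate
#'   columns (see [read_covariates()]).
#' @return A tibble with columns `covariate`, `subgroup`, `n_members`,
#'   `n_available`, `mean`. Subgroups with no members (or no non-missing
#'   values) get `mean = NA`.
#' @export
covariate_summaries <- function(assignments, covariates) {
  m <- membership_matrix(assignments)
  idx <- match(rownames(m), covariates$patient_id)
  cov_names <- setdiff(names(covariates), "patient_id")
  rows <- list()
  for (cv in cov_names) {
    v <- covariates[[cv]][idx]
    for (j in seq_len(ncol(m))) {
      mem <- m[, j]
      vv <- v[mem]
      n_avail <- sum(!is.na(vv))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        covariate = cv, subgroup = colnames(m)[j],
        n_members = sum(mem), n_available = n_avail,
        mean = if (n_avail > 0L) mean(vv, na.rm = TRUE) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
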