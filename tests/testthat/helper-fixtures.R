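# Small builders shared across test files.

# readings tibble for one patient from a weight vector (days 0-based)
one_series <- function(weights, id = "p1", days = seq_along(weights) - 1L) {
  tibble::tibble(patient_id = id, day = as.integer(days), weight = weights)
}

# readings tibble from a named list of weight vectors
make_readings <- function(series) {
  do.call(rbind, lapply(names(series), function(id)
    one_series(series[[id]], id = id)))
}

# a patient guaranteed into exactly the given subgroup: constant residue
pure_class_series <- function(id, residue, n = 162L, base = 150L) {
  one_series(rep(base + residue, n), id = id)
}

# covariate-effects table used by several generator tests
example_covariate_effects <- function() {
  tibble::tibble(
    covariate = c("age", "male"),
    type = c("continuous", "binary"),
    edp = c(60, 0.69), nedp = c(64, 0.55),
    sd = c(14, NA))
}

# write a readings CSV and return its path
write_fixture_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}
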