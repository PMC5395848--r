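Package: enddigit
Title: End-Digit Preference Detection in Self-Reported Telemonitoring
    Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and quantify end-digit preference (the habit
    of reporting values ending in 0 or 5) in self-reported daily weights
    from heart-failure telemonitoring programmes.  Implements
    reading-level rounding diagnostics (remainder distributions,
    chi-squared uniformity tests, excess-multiples estimates, logistic
    time trends, divisor-specificity checks), a per-patient subgroup
    assignment scheme based on one-sided binomial proportion tests, a
    two-stage subtraction estimator of the number and baseline
    characteristics of patients with end-digit preference with
    patient-level bootstrap confidence intervals, retrospective
    telemonitoring alert algorithms, and a simulation framework with
    ground-truth labels and a closed-form assignment-probability oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
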