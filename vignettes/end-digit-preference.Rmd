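---
title: "Detecting end-digit preference in self-reported telemonitoring weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting end-digit preference in self-reported telemonitoring weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enddigit)
```

## The problem

Heart-failure telemonitoring programmes ask patients to weigh themselves
daily and relay the value, often by typing a whole number into a telephone
keypad. Clinicians treat a change of two or three pounds as actionable,
because fluid build-up precedes decompensation. A patient who habitually
rounds to the nearest five pounds ("end-digit preference", EDP) destroys
exactly the signal the service depends on: a true change from 142 to
143 lb reported as 140 then 145 triggers a false alert, and a true change
from 143 to 147 lb reported as 145 twice hides a real one. Because home
weights have no gold standard, the package borrows the logic of fraud
detection: test whether the *distribution of final digits* is compatible
with accurate reporting, and work out how many patients, and which kinds
of patients, drive any deviation.

## Reading-level diagnostics

Every reported weight is reduced to a residue class
`floor(weight) mod 5` in `{0, 1, 2, 3, 4}`; class 0 collects the weights
ending in 0 or 5. If everyone reported accurately, the five classes would
be (very nearly) equally likely, so three diagnostics follow directly:

* `uniformity_chisq()` — a Pearson chi-squared test of the five class
  counts against uniformity (df = 4);
* `excess_multiples()` — the number of readings affected by rounding,
  estimated as the class-0 count minus the chance expectation
  (one-fifth of all readings). A deficit is reported as-is, flagged,
  never clipped;
* `multiple_of_five_trend()` — a reading-level logistic regression of
  "is a multiple of five" on days since enrolment, reported as an odds
  ratio per day with a Wald interval. Each reading contributes one
  Bernoulli observation; this matches a reading-level analysis and
  ignores within-patient correlation, so a cluster-robust variance
  (by patient, via the sandwich estimator) is available behind
  `cluster = TRUE` but off by default.

`divisor_sensitivity()` repeats the excess analysis for other small
primes. Genuine five-preference should light up divisor 5 only; divisor
2 partially inherits the signal (multiples of ten are even), which is why
3 and 7 are the cleaner negative controls.

## From readings to patients: subgroups A0–A4

Counting affected *readings* is not the same as counting affected
*patients*: a patient whose true weight is stable near a multiple of five
reports many class-0 values innocently. The package therefore tests each
patient separately. For patient with $n$ readings and $k_r$ readings in
class $r$, the share $k_r/n$ is compared with the chance rate $p_0 = 0.2$
using a one-sided proportion test; the patient joins subgroup $A_r$
whenever the p-value is strictly below $\alpha = 0.05$. Membership is not
exclusive and may be empty.

The default test is the **score test without continuity correction**,
$z = (k/n - p_0)\big/\sqrt{p_0(1-p_0)/n}$, upper normal tail. The choice
matters at small $n$: the score test gives rejection thresholds
$k^*(10) = 5$, $k^*(20) = 7$, $k^*(40) = 13$, and with these thresholds
the closed-form assignment probabilities for a rounding patient
(0.423, 0.956, 0.998 at 10/20/40 reporting days — see the oracle below)
match the simulation behaviour this scheme is known for. The exact
binomial test is more conservative ($k^*(20) = 8$, assignment probability
0.80 rather than 0.96) and remains available via
`edp_config(test = "exact")`, with the caveat that all small-sample
operating characteristics shift. No minimum-readings filter and no
multiplicity correction across the five tests are applied: sparse
patients simply rarely reject, and the estimator's symmetry argument
absorbs the per-class false-positive rate.

$A_0$ is designed to be a *superset* of the EDP group: it catches
essentially every rounder with enough readings, plus some innocent
patients. Subgroups $A_1$–$A_4$ estimate that innocent contamination,
because a patient without digit preference is equally likely to land in
any of the five subgroups by chance.

## The two-stage subtraction estimator

With $n_r$ the size of $A_r$ and $x_r$ a per-subgroup covariate mean, the
estimators are

$$\hat N_{EDP} = n_0 - \tfrac14\sum_{i=1}^{4} n_i, \qquad
  \hat x_{EDP} = \frac{n_0 x_0 - \tfrac14\sum_{i=1}^4 n_i x_i}
                      {n_0 - \tfrac14\sum_{i=1}^4 n_i},$$

and the NEDP characteristic is the pooled $A_1$–$A_4$ mean
$\sum n_i x_i / \sum n_i$. The NEDP *count* is the $A_0$ remainder after
removing the estimated EDP patients plus everyone in $A_1$–$A_4$. Both
estimators are conservative: EDP patients missed by $A_0$, or leaking
into $A_1$–$A_4$ (which happens when weights are nearly constant),
shrink $\hat N_{EDP}$ and attenuate EDP–NEDP contrasts toward the null —
they do not flip their sign. Useful identities, both tested: if all
$x_r$ are equal the EDP and NEDP means collapse to that common value, and
$\hat N_{EDP}\,\hat x_{EDP} + \tfrac14\!\left(\sum n_i\right)\bar x_{1\text{–}4} = n_0 x_0$.

A worked example with subgroup sizes (212, 96, 107, 130, 95) over 707
patients gives $\hat N_{EDP} = 212 - 107 = 105$ (14.9%), an NEDP count of
535, and — with subgroup mean ages (62.1, 66.1, 65.1, 63.1, 62.1) — an
EDP mean age of 60.1 versus a pooled NEDP mean of 64.1 (the pooled value
sits at 64.05 and is sensitive to the rounding of its inputs at the first
decimal). Binary covariates travel through the same formulas as member
proportions, e.g. male counts (131, 57, 63, 66, 50) give an EDP male
share of 68.6%.

**Bootstrap.** Confidence intervals resample *patients* (their whole
reading series together with their covariates) with replacement to the
original size, recompute subgroup assignment and every estimator on each
replica, and take percentile 2.5/97.5 limits; `B = 1000` by default.
Because assignment is a deterministic function of one patient's readings,
resampling assignment rows is exactly equivalent to re-running the tests
on resampled series, which is what `edp_bootstrap()` exploits.
Replicates where an estimator is undefined (non-positive estimated EDP
count, empty $A_1$–$A_4$ pool) are excluded and counted, never imputed.
The percentile method was chosen over BCa for transparency at the small
subgroup counts involved; missing covariate values are handled
available-case per covariate throughout, so each summary carries its own
denominator.

Two definitional choices are deliberate and configurable: the EDP
*fraction* divides by all patients who submitted data (not just subgroup
members), and duplicate same-day submissions are rejected at parse time
rather than silently collapsed, because any collapsing rule would bias
the per-patient proportions in an unverifiable way.

## Alert algorithms

Two retrospective alerting rules are implemented:

* `telehf_alerts()` — deviation of at least 3 lb in either direction
  from the *first recorded weight*; the baseline reading itself cannot
  alert. An alert is suppressed when the immediately preceding *calendar*
  day alerted and the weight is unchanged; after a missed day an
  unchanged out-of-range weight alerts again. Written descriptions of
  this rule vary between "at least three pounds" and "more than three
  pounds"; the default is `>=` with a `strict = TRUE` flag for `>`, and
  `suppression = "submission"` switches to previous-submission
  semantics. The baseline is never reset.
* `daydelta_alerts()` — change of strictly more than 2 lb between
  consecutive calendar days; reporting gaps produce no alert because the
  day-on-day change is unobserved. For integer weights "> 2" coincides
  with ">= 3" (a tested equivalence).

`group_alert_summary()` treats each patient's alert count as a covariate
and pushes it through the same weighted-average estimators and bootstrap,
yielding EDP and NEDP mean alert rates; `within_person_variance()` does
the analogous thing for weight variability (sample variance, $n-1$;
single-reading patients excluded available-case).

## The synthetic cohort generator

Because real telemonitoring submissions are not redistributable, every
downstream stage is exercised on synthetic cohorts with known ground
truth, generated by `generate_cohort()`:

* **True weights** follow a zero-drift Gaussian random walk,
  $w_t = w_{t-1} + N(0, \sigma^2)$, with $\sigma$ (`sd_daily`) spanning
  0 (constant weight) to 1 lb/day; starting weights are uniform on
  120–220 lb, which makes the starting residue uniform on
  $\{0,\dots,4\}$. The **limiting mode** replaces the walk with iid
  uniform integer weights on 120–224 lb — the regime a high-volatility
  walk converges to modulo 5. The range spans 105 = 3·5·7 values so that
  residues are *exactly* uniform modulo 3, 5 and 7, keeping the
  divisor-specificity controls clean.
* **Reporting.** Non-rounded days report the integer part of the true
  weight (keypad entry truncates; nearest-integer is available via
  `report_style = "round"`). An EDP patient rounds exactly
  `round(q * n)` of their `n` reporting days — chosen uniformly at
  random, independently of the weight values — to the nearest multiple
  of five; exact midpoints (2.5 mod 5) round up, deterministically. The
  fixed-count model is the default because the closed-form assignment
  probabilities it implies (0.423 at 10 days with $q = 0.3$) reproduce
  the known small-sample operating characteristics of the assignment
  scheme, whereas iid per-day Bernoulli($q$) rounding gives visibly
  different values (0.470 at the same design point); the Bernoulli model
  is retained as `rounding_model = "bernoulli"`. For `round(q * n)` the
  default round-half-to-even is used (49 of 162 days at $q = 0.3$);
  floor would give 48, and both are indistinguishable at trial-average
  compliance.
* **Study conditions.** Defaults mirror the conditions the analysis was
  designed for: 162 reporting days (the trial-average compliance over a
  180-day window), 15% of patients labelled EDP, rounding on 30% of
  days, scenario grids over EDP fractions {15, 30, 60}%, rounding
  fractions {30, 50, 70}%, volatilities {0, 0.05, 0.1, 0.5, 1,
  limiting} and compliance {10, 20, 40, 60, 80, 162, 180} days, with
  10,000 patients per scenario. Covariate distributions may differ by
  group (`covariate_effects`), e.g. EDP patients younger and more often
  male.
* **Ground truth** records each patient's label and rounded days, so
  assignment rates, estimator bias and bootstrap coverage are all
  directly measurable.

What the generator does *not* emulate: physiological structure (diurnal
variation, decompensation episodes, drift under diuretic titration),
missingness that is informative about health status, digit preferences
other than fives, and transcription errors that are not rounding. Green
tests therefore demonstrate that the estimator recovers the truth under
its own stated assumptions — symmetric chance assignment and
high-volatility weights — not that those assumptions hold in any
particular clinical data set.

## The closed-form oracle

`closed_form_assignment_prob(n, q)` gives an independent check on the
whole simulation layer: under limiting-mode residues and fixed-count
rounding, a rounding patient's class-0 count is
$m + \mathrm{Binom}(n - m, 0.2)$ with $m = \mathrm{round}(qn)$, so the
probability of joining $A_0$ is $P(\mathrm{Binom}(n-m, 0.2) \ge k^*(n) - m)$.
`closed_form_null_prob(n)` is the analogous chance-assignment rate
$P(\mathrm{Binom}(n, 0.2) \ge k^*(n))$ — about 0.059 per class at
$n = 162$, which is why roughly 70% of non-rounding patients join no
subgroup at all. Simulated rates are required to sit within three
Monte-Carlo standard errors of these closed forms.

## Numerical and testing choices

Degenerate inputs are surfaced, not patched: a constant trend outcome is
flagged non-estimable instead of erroring, a negative excess or EDP count
carries a flag, an all-unavailable bootstrap warns. Determinism is
end-to-end: a cohort seed fixes the cohort byte-for-byte (draw order:
labels, then per patient path and rounding days, then covariates), and a
config seed fixes every bootstrap interval.

The test suite sizes its Monte-Carlo experiments to keep the full run
around half a minute while leaving comfortable statistical margins:
uniformity and calibration checks use cohorts of 40–3,000 patients with
3-standard-error bands, the grid reproductions use 10,000 patients
(matching the scenario definition) for the cells quoted above and
1,200–2,000 patients elsewhere, trend recovery uses $10^5$ readings at a
per-day odds ratio of 1.002, and bootstrap coverage of the true EDP
fraction uses 100 outer cohorts of 250 patients with $B = 300$.

## Limitations

The estimator is a deliberate lower bound; occasional rounders and
low-compliance rounders are missed by construction. Characteristic
contrasts are attenuated whenever weights are very stable
(below roughly 0.5 lb/day the $A_1$–$A_4$ pool picks up EDP patients).
Alert comparisons between EDP and NEDP groups cannot be adjusted for
baseline differences. A latent-variable formulation of digit preference
would use all readings jointly rather than a per-patient threshold test,
at the cost of distributional assumptions; it is out of scope here.
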