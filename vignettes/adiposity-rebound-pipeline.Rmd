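---
title: "Adiposity rebound timing from scheduled check-up data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adiposity rebound timing from scheduled check-up data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmirebound)
```

## The problem

The adiposity rebound (AR) — the second rise of BMI after its
early-childhood minimum — is ordinarily timed by fitting a smooth curve to
densely measured BMI and locating its turning point. Registry check-up
data offer no such luxury: each child is seen at most seven times, at
median ages 5, 11, 21, 33, 45, 57 and 69 months, by many different
primary-care measurers. The pipeline therefore adopts the coarse but
transparent estimator used in large national-cohort studies: the nadir is
the *exam* with the lowest valid BMI, and AR timing is the class of that
exam — very early (exams I–V, up to 45 months), early (exam VI, 57
months), moderate-to-late (exam VII, 69 months).

Two consequences of this estimator shape everything downstream. First,
because the grid is coarse, the recovered nadir age is biased early
relative to the true turning point of the underlying curve. Second, a
child whose true nadir lies beyond 69 months is indistinguishable from one
rebounding exactly at exam VII; both are "moderate-to-late". The package
classifies what the design can see and does not extrapolate.

One wording subtlety is resolved in favour of the published table
arithmetic: "very early" is described as rebound *before* 45 months yet the
published per-exam prevalences only sum to the published very-early share
when exam V (45 months) is *included*. The classifier therefore maps exams
I–V to very early, and this is fixed, not an option.

## Quality control

Measurements must be present, height ≥ 25 cm, weight ≥ birth weight, and
both must have *increased* versus the previous exam; children need an
in-range birth weight (0.5–5.0 kg, both ends inclusive) and at least five
valid exams. Three under-specified corners required decisions:

- **"Increased" = strictly greater.** Ties count as not increased
  (`strict = FALSE` switches to ≥).
- **Baseline after an invalid exam = last *valid* exam.** A corrupted
  record (say, a height typed 10 cm short) should invalidate itself, not
  every subsequent comparison. When no prior valid exam exists, the floors
  themselves (25 cm, birth weight, inclusive) act as the baseline — this
  also defines exam I.
- **Missing birth weight = excluded** with the birth-weight reason; the
  sequential weight rule is undefined without it.

The exclusion report partitions its input exactly
(`n_input = excluded_bw + excluded_few + included`), which the tests check
against an independent per-subject re-scan written as a plain loop.

## Nadir identifiability and ties

A nadir is unidentifiable iff exam VII is missing or invalid: without the
final observation, a minimum at the last *observed* exam cannot be
distinguished from a still-falling trajectory. Unidentifiable children are
excluded from prevalence denominators (mirroring the source study's
accounting, where 16,207 of 27,143 children were classifiable). Ties are
broken to the earliest tying exam — conservative toward earlier AR — with
a flag set and a `tie = "latest"` switch for sensitivity analysis.

## The synthetic world

The generator is a first-class module, not a fixture: its defaults *are*
the stated world, chosen once and not tuned to test outcomes.

Per child, BMI follows a piecewise-quadratic curve — rise from birth BMI
$B_0$ to peak $B_{peak}$ at $t_{peak}$, quadratic fall to nadir $B_R$ at
$t_R$, quadratic rebound with curvature $k$ — guaranteeing a single
interior minimum exactly at $t_R$. Height follows the classical
Jenss–Bayley form $h(t) = A + Bt - Ce^{-Dt}$, monotone increasing for the
sampled parameter ranges; weight is implied, $w = BMI\,(h/100)^2$.

Key defaults, with the reasoning where no anchor existed:

| parameter | default | why |
|---|---|---|
| birth weight | TruncN(3.2, 0.45²) kg on [0.4, 5.5] | gives ≈6% ≤2.5 kg, matching the LBW share of the source cohort |
| nadir BMI $B_R$ | N(15.9, 1.3²) | anchored to the published cohort mean at 45–57 months |
| peak − nadir gap | TruncN(2.0, 0.6²), ≥0.3 | peak mean ≈17.9, near the published 17.8 at 5 months |
| nadir age $t_R$ | logN(ln 48, 0.35²) months | median 48 ≈ the published median nadir exam (45 mo); the lognormal tail puts ≈15% of true nadirs past 69 months, emulating the moderate-to-late group |
| rebound curvature $k$ | logN(ln 0.0015, 0.5²) | ≈0.2 kg/m² per year² shortly after rebound, a plausible post-AR velocity |
| noise | 0.5 cm, 0.15 kg | clinic-scale measurement error |
| corruption | p_miss 0.05, p_shrink 0.01, p_bw_out 0.002 per exam/subject | enough to exercise every filter without dominating the cohort |

No published dispersion existed for cohort BMI at each exam, so the
between-child SDs are calibration choices; the one anchored requirement —
cohort mean BMI at 45 months within ±0.5 of 15.9 — is met (≈16.1 at
n = 20,000).

Mechanism independence: parameter sampling, measurement noise, corruption
and (optional) age jitter each consume their own seeded stream with
fixed-length draws, so switching one mechanism off does not move any other
mechanism's draws. Corruptions are applied in the documented order noise →
height shrink → exam drop-out → birth-weight replacement, and the truth
table logs all of them plus the noise-free argmin exam.

What the generator does **not** emulate — so a green test does not
establish robustness to it: secular trends and seasonality; correlated
missingness (drop-out is independent per exam, real families miss runs of
visits); digit-preference and device rounding; the correlation between
birth weight and the subsequent curve (the recorded birth weight and the
weight curve are sampled independently, so birth weight is a pure nuisance
covariate in the simulated world); sex differences in trajectory shape
(sex is a label, identical distributions); gestational age. The
exam-I share of nadirs (~5%) is also higher than in the real cohort
(0.2%), because low-peak children can start below their later curve — the
generator's single anchored moment is the 45-month mean, not the full
per-exam profile.

## Statistical layer

- χ² and likelihood-ratio G tests use the textbook formulas with no
  continuity correction (every correction in the package is an explicit
  flag, all off by default).
- Odds ratios are Wald-type, symmetric on the log scale, matching the
  interval style of the source tables. The "multiple logistic regression"
  of the 3-level outcome is implemented as *binary* logistic on the
  indicator of AR before 57 months (very early or early), exactly the
  outcome of the published OR column; the 3-level tables are handled by
  χ²/G. Multinomial logit is a deliberate non-goal. Exposures are forced
  to treatment contrasts (an ordered factor would silently fit polynomial
  terms), and separation is flagged, never silently reported.
- Sex comparisons use Welch's unequal-variance t rather than the pooled
  test: at registry n the difference is negligible and the robust default
  costs nothing.
- Percentiles use the type-7 (linear interpolation between order
  statistics) convention throughout, fixed because thresholds at small n
  depend on it. A consequence worth stating: duplicating an entire cohort
  shifts type-7 quantiles by O(1/n) — exact duplication invariance holds
  only for ECDF-style quantile types — so the tests assert approximate,
  not exact, invariance.
- Weight-status thresholds default to *within-cohort* sex-stratified
  percentiles at exam VI (the source study does not name its reference);
  an external sex × percentile threshold table can be supplied instead.
  With within-cohort thresholds the realized category frequencies are
  pinned near 5/80/10/5% by construction — that check validates the
  classification plumbing, not the population.
- Table-2-style analyses have a smaller denominator than prevalence
  analyses (a valid exam-VI BMI is additionally required); both
  denominators are reported rather than reconciled, as the source tables
  themselves differ.

## Degenerate inputs and numerics

Empty cohorts yield zeroed reports, not errors; a cohort with only headers
parses to an empty cohort with a warning; malformed CSV rows are routed to
a reject file with line numbers, never dropped silently. Logistic fitting
uses IRLS to tolerance 1e-8, max 100 iterations. All-zero SDs in the
simulator are honoured exactly (point masses), which the tests use to pin
the configured means. The simulator emits full-precision measurements:
rounding to instrument precision would act as extra noise and break the
exact noise-free truth-recovery guarantee near BMI ties.

## Known limitations

The estimator cannot see nadirs after 69 months; AR timing classes are
exam-grid classes, not ages; the unidentifiability rule cannot be
validated against the source cohort's exact classifiable count without the
restricted data; and the synthetic world's associations (e.g. obesity at
57 months vs early AR) emerge from the curve geometry, not from an
explicit causal model — they are suitable for testing machinery, not for
effect-size benchmarking.
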