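Package: bmirebound
Title: Adiposity Rebound Timing from Longitudinal Infant Check-Up Data
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for longitudinal BMI-trajectory analysis of
    scheduled infant and early-childhood health check-up records: record- and
    subject-level quality filters for anthropometry sequences, detection of the
    per-child BMI nadir across the exam schedule and classification of
    adiposity-rebound timing (very early, early, moderate-to-late), birth-weight
    and rapid-weight-gain and BMI-status subgrouping, empirical growth
    percentile-curve construction, contingency-table tests and crude and
    covariate-adjusted odds ratios, plus a seeded synthetic-cohort generator
    with per-child ground truth so the whole pipeline can be exercised and
    validated without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
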