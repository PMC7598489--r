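test_that("crosstab counts exactly and reports exclusions", {
  d <- data.frame(
    row = factor(rep(c("a", "b"), each = 6)),
    col = factor(rep(rep(c("x", "y", "z"), each = 2), 2))
  )
  tab <- crosstab(d, "row", "col")
  expect_true(all(tab$counts == 2L))
  expect_equal(unname(tab$row_margin), c(6, 6))
  expect_equal(unname(tab$col_margin), c(4, 4, 4))
  expect_equal(tab$n, 12)
  expect_equal(tab$n_excluded, 0)

  d$col[1] <- NA
  tab2 <- crosstab(d, "row", "col")
  expect_equal(tab2$n, 11)
  expect_equal(tab2$n_excluded, 1)
  expect_error(crosstab(d, "row", "nope"), "unknown factor")

  empty <- d[0, ]
  tab0 <- crosstab(empty, "row", "col")
  expect_equal(tab0$n, 0)
  expect_true(all(tab0$counts == 0))
})

test_that("crosstab is permutation-invariant and conserves counts", {
  run <- make_clean(n = 400, seed = 111)
  cls <- classify_cohort(run$clean)
  sg <- subgroup_table(run$clean)
  d <- merge(sg, cls, by = "id")
  d <- d[d$ar_class != "unclassified" & !is.na(d$bmi_status), ]
  t1 <- crosstab(d, "bmi_status", "ar_class")
  set.seed(3)
  t2 <- crosstab(d[sample(nrow(d)), ], "bmi_status", "ar_class")
  expect_identical(t1$counts, t2$counts)
  expect_equal(sum(t1$counts), nrow(d))
})

test_that("Pearson statistic matches hand and brute-force computation", {
  even <- matrix(c(10, 10, 10, 10), 2)
  res <- chi_square(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  skew <- matrix(c(20, 10, 10, 20), 2)
  res2 <- chi_square(skew)
  expect_equal(res2$statistic, 20 / 3, tolerance = 1e-12)  # 6.667
  expect_equal(res2$df, 1)

  set.seed(13)
  for (i in 1:10) {
    O <- matrix(rpois(12, 30) + 1, 3, 4)
    expect_equal(chi_square(O)$statistic, oracle_chisq(O))
  }
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("likelihood-ratio statistic matches direct evaluation", {
  indep <- outer(c(20, 10), c(2, 1)) / 1  # rank-1 table: O == E
  expect_equal(likelihood_ratio_test(indep)$statistic, 0, tolerance = 1e-12)

  skew <- matrix(c(20, 10, 10, 20), 2)
  g_hand <- 2 * (2 * 20 * log(20 / 15) + 2 * 10 * log(10 / 15))
  res <- likelihood_ratio_test(skew)
  expect_equal(res$statistic, g_hand)
  expect_equal(round(res$statistic, 3), 6.796)

  # asymptotic agreement with Pearson near independence
  set.seed(29)
  big <- outer(c(400, 600), c(0.3, 0.7)) + matrix(rpois(4, 4), 2)
  expect_lt(abs(chi_square(big)$statistic -
                  likelihood_ratio_test(big)$statistic), 0.2)
})

test_that("crude odds ratio and Wald interval follow the closed form", {
  res <- crude_or(matrix(c(90, 50, 10, 50), 2))
  expect_equal(res$or, 9.0)
  se <- sqrt(1 / 90 + 1 / 10 + 1 / 50 + 1 / 50)
  expect_equal(res$ci_low, exp(log(9) - qnorm(0.975) * se))
  expect_equal(res$ci_high, exp(log(9) + qnorm(0.975) * se))

  flat <- crude_or(matrix(c(25, 25, 25, 25), 2))
  expect_equal(flat$or, 1.0)
  expect_true(flat$ci_low < 1 && flat$ci_high > 1)

  expect_error(crude_or(matrix(c(0, 5, 5, 5), 2)), "zero cell")
  expect_no_error(crude_or(matrix(c(0, 5, 5, 5), 2), haldane = TRUE))
})

test_that("single-binary-exposure logistic reproduces the crude OR exactly", {
  set.seed(37)
  d <- data.frame(
    exposed = rep(c(TRUE, FALSE), times = c(400, 600))
  )
  d$out <- rbinom(1000, 1, ifelse(d$exposed, 0.45, 0.25)) == 1
  tab <- table(factor(d$exposed, c(TRUE, FALSE)),
               factor(d$out, c(TRUE, FALSE)))
  crude <- crude_or(unclass(tab))
  d$exposed_f <- factor(d$exposed, levels = c(FALSE, TRUE))
  fit <- fit_logistic(d, "out", "exposed_f")
  expect_equal(fit$or, crude$or, tolerance = 1e-6)
  expect_equal(fit$ci_low, crude$ci_low, tolerance = 1e-6)
  expect_equal(fit$ci_high, crude$ci_high, tolerance = 1e-6)
})

test_that("an irrelevant covariate barely moves the exposure OR", {
  set.seed(41)
  n <- 5000
  d <- data.frame(exposed = factor(rbinom(n, 1, 0.4)))
  d$out <- rbinom(n, 1, ifelse(d$exposed == 1, 0.4, 0.25)) == 1
  d$noise <- rnorm(n)
  plain <- fit_logistic(d, "out", "exposed")
  adj <- fit_logistic(d, "out", "exposed", covariates = "noise")
  expect_equal(adj$or, plain$or, tolerance = 0.02)
})

test_that("Wald interval covers the null at its nominal rate", {
  set.seed(43)
  n <- 5000
  cover <- vapply(1:100, function(i) {
    d <- data.frame(exposed = factor(rbinom(n, 1, 0.5)))
    d$out <- rbinom(n, 1, 0.3) == 1
    f <- fit_logistic(d, "out", "exposed")
    f$ci_low <= 1 && 1 <= f$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("separation is flagged, not silently reported", {
  d <- data.frame(exposed = factor(rep(c(0, 1), each = 30)),
                  out = rep(c(FALSE, TRUE), each = 30))
  fit <- fit_logistic(d, "out", "exposed")
  expect_true(fit$flagged)
})

test_that("percentile curves are ordered and duplication-invariant", {
  run <- make_clean(n = 600, seed = 121)
  pc <- percentile_curves(run$clean, sex = "male")
  expect_equal(nrow(pc), 7 * 13)
  for (j in 1:7) {
    expect_true(all(diff(pc$bmi[pc$exam_index == j]) >= 0))
  }

  clean2 <- run$clean
  clean2$subjects <- rbind(
    clean2$subjects,
    transform(clean2$subjects, id = id + 1e6)
  )
  clean2$exams <- rbind(clean2$exams, transform(clean2$exams, id = id + 1e6))
  # type-7 quantiles interpolate order statistics, so duplication shifts the
  # plotting positions by O(1/n): invariance is approximate, and loosest at
  # the extreme levels where tail order-statistic gaps are wide
  pc2 <- percentile_curves(clean2, sex = "male")
  interior <- pc$level >= 10 & pc$level <= 95
  expect_lt(max(abs(pc2$bmi[interior] - pc$bmi[interior])), 0.15)
  expect_lt(mean(abs(pc2$bmi - pc$bmi)), 0.05)

  tiny <- run$clean
  keep <- tiny$subjects$id[1:30]
  tiny$subjects <- tiny$subjects[tiny$subjects$id %in% keep, ]
  tiny$exams <- tiny$exams[tiny$exams$id %in% keep, ]
  expect_error(percentile_curves(tiny), "too few")
})

test_that("sex comparison reduces to the Welch formula", {
  clean <- structure(list(
    subjects = data.frame(id = 1:6,
                          sex = rep(c("male", "female"), each = 3),
                          birth_weight_kg = 3.2),
    exams = data.frame(id = 1:6, exam_index = 1, age_months = 5,
                       height_cm = 60, weight_kg = 6, valid = TRUE,
                       invalid_reason = "none",
                       bmi = c(17.1, 17.9, 18.4, 16.8, 17.2, 17.0))
  ), class = "clean_cohort")
  res <- sex_compare(clean, exam_ages = 5)
  m <- c(17.1, 17.9, 18.4); f <- c(16.8, 17.2, 17.0)
  t_hand <- (mean(m) - mean(f)) / sqrt(var(m) / 3 + var(f) / 3)
  expect_equal(res$t[1], t_hand)

  # identical distributions: t exactly zero
  clean$exams$bmi <- rep(c(16, 17, 18), 2)
  res0 <- sex_compare(clean, exam_ages = 5)
  expect_equal(res0$t[1], 0)
  expect_equal(res0$p.value[1], 1)
})

test_that("a strong simulated sex difference is detected at every exam", {
  set.seed(47)
  n <- 2000
  detected <- vapply(1:20, function(i) {
    clean <- structure(list(
      subjects = data.frame(id = seq_len(2 * n),
                            sex = rep(c("male", "female"), each = n)),
      exams = data.frame(id = seq_len(2 * n), exam_index = 1,
                         age_months = 5, height_cm = 60, weight_kg = 6,
                         valid = TRUE, invalid_reason = "none",
                         bmi = c(rnorm(n, 16.4, 1.3), rnorm(n, 15.9, 1.3)))
    ), class = "clean_cohort")
    sex_compare(clean, exam_ages = 5)$p.value[1] < 0.001
  }, logical(1))
  expect_true(all(detected))
})
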