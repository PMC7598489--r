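make_subject_exams <- function(h, w, idx = seq_along(h)) {
  data.frame(exam_index = idx, age_months = EXAM_AGES_T[idx],
             height_cm = h, weight_kg = w)
}
EXAM_AGES_T <- c(5, 11, 21, 33, 45, 57, 69)

test_that("birth-weight bounds are inclusive at both ends", {
  expect_true(check_birth_weight(0.5))
  expect_true(check_birth_weight(5.0))
  expect_true(check_birth_weight(3.2))
  expect_false(check_birth_weight(5.01))
  expect_false(check_birth_weight(0.49))
  expect_error(check_birth_weight(NA_real_), "missing")
  expect_error(check_birth_weight("3"), "numeric")
})

test_that("BMI arithmetic is weight over squared height in metres", {
  expect_equal(compute_bmi(100, 16.0), 16.0)
  expect_equal(compute_bmi(50, 3.25), 13.0)
  expect_equal(compute_bmi(110, 19.36), 16.0)
  expect_error(compute_bmi(0, 10), "positive")
})

test_that("sequential screen skips shrunk records without poisoning later ones", {
  h <- c(55, 70, 68, 90, 95, 100, 105)
  w <- c(7, 9, 10, 12, 13, 14, 15)
  res <- validate_sequence(make_subject_exams(h, w), birth_weight = 3.2)
  expect_equal(res$valid, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(res$invalid_reason[3], "height_not_increased")
  # exam 4 was compared against exam 2 (70 cm), not the invalid 68 cm
  h2 <- c(55, 70, 68, 69, 95, 100, 105)
  res2 <- validate_sequence(make_subject_exams(h2, w), birth_weight = 3.2)
  expect_false(res2$valid[4])
  expect_equal(res2$invalid_reason[4], "height_not_increased")
})

test_that("floors apply at exam I and reasons follow the fixed order", {
  res <- validate_sequence(
    make_subject_exams(c(24.9, 60), c(7, 8), idx = 1:2), birth_weight = 3.2
  )
  expect_false(res$valid[1])
  expect_equal(res$invalid_reason[1], "height_below_min")
  # after an invalid exam I, exam II is checked against the floors and passes
  expect_true(res$valid[2])

  res_w <- validate_sequence(
    make_subject_exams(55, 3.0, idx = 1), birth_weight = 3.2
  )
  expect_equal(res_w$invalid_reason[1], "weight_below_birth")

  res_m <- validate_sequence(
    make_subject_exams(c(55, 70), c(7, 9), idx = c(1, 3)), birth_weight = 3.2
  )
  expect_equal(res_m$invalid_reason[2], "missing")
})

test_that("a fully increasing sequence is fully valid", {
  res <- validate_sequence(
    make_subject_exams(c(55, 70, 80, 90, 95, 100, 105), 7:13),
    birth_weight = 3.2
  )
  expect_true(all(res$valid))
  expect_true(all(res$invalid_reason == "none"))
})

test_that("non-strict mode accepts ties", {
  h <- c(55, 55, 80, 90, 95, 100, 105)
  w <- 7:13
  strict <- validate_sequence(make_subject_exams(h, w), 3.2, strict = TRUE)
  lax <- validate_sequence(make_subject_exams(h, w), 3.2, strict = FALSE)
  expect_false(strict$valid[2])
  expect_true(lax$valid[2])
})

test_that("malformed exam sequences are rejected", {
  bad <- make_subject_exams(c(55, 60), c(7, 8), idx = c(2, 1))
  expect_error(validate_sequence(bad, 3.2), "sorted")
  dup <- make_subject_exams(c(55, 60), c(7, 8), idx = c(1, 1))
  expect_error(validate_sequence(dup, 3.2), "sorted")
})

test_that("subject inclusion boundary sits at five valid exams", {
  subj <- data.frame(id = 1:3, sex = "male",
                     birth_weight_kg = c(3.2, 3.2, 6.0))
  five_valid <- data.frame(
    id = 1, exam_index = 1:5, age_months = EXAM_AGES_T[1:5],
    height_cm = c(55, 70, 80, 90, 95), weight_kg = 7:11
  )
  four_valid <- data.frame(
    id = 2, exam_index = 1:4, age_months = EXAM_AGES_T[1:4],
    height_cm = c(55, 70, 80, 90), weight_kg = 7:10
  )
  heavy <- data.frame(
    id = 3, exam_index = 1:7, age_months = EXAM_AGES_T,
    height_cm = c(55, 70, 80, 90, 95, 100, 105), weight_kg = 7:13
  )
  qc <- apply_qc(subj, rbind(five_valid, four_valid, heavy))
  expect_equal(qc$subjects$included, c(TRUE, FALSE, FALSE))
  expect_equal(qc$subjects$exclusion_reason,
               c("none", "fewer_than_5_valid", "birth_weight_out_of_range"))
  expect_equal(qc$report$n_input, 3)
  expect_equal(qc$report$n_excluded_birth_weight +
                 qc$report$n_excluded_too_few_valid +
                 qc$report$n_included, 3)
})

test_that("QC is idempotent and order-invariant on simulated cohorts", {
  run <- make_clean(n = 400, seed = 31)
  qc1 <- run$qc
  clean <- run$clean
  # idempotence: re-screening the included subjects excludes nobody new
  valid_only <- clean$exams[!is.na(clean$exams$valid) & clean$exams$valid,
                            c("id", "exam_index", "age_months",
                              "height_cm", "weight_kg")]
  qc2 <- apply_qc(clean$subjects[c("id", "sex", "birth_weight_kg")],
                  valid_only)
  expect_equal(qc2$report$n_included, nrow(clean$subjects))
  expect_equal(qc2$report$n_excluded_too_few_valid, 0)

  # order invariance: shuffle subject and exam rows
  co <- run$cohort
  set.seed(99)
  perm_s <- sample(nrow(co$subjects))
  perm_e <- sample(nrow(co$exams))
  qc3 <- apply_qc(co$subjects[perm_s, ], co$exams[perm_e, ])
  m <- match(co$subjects$id, qc3$subjects$id)
  expect_equal(qc3$subjects$included[m], qc1$subjects$included)
})

test_that("exclusion accounting matches the brute-force oracle", {
  co <- generate_cohort(sim_config(
    n_subjects = 800, seed = 41, p_miss = 0.15, p_shrink = 0.08,
    p_bw_out = 0.03
  ))
  qc <- apply_qc(co$subjects, co$exams)
  oracle <- oracle_qc_counts(co$subjects, co$exams)
  expect_equal(qc$report$n_excluded_birth_weight,
               unname(oracle["birth_weight"]))
  expect_equal(qc$report$n_excluded_too_few_valid, unname(oracle["too_few"]))
  expect_equal(qc$report$n_included, unname(oracle["included"]))
})

test_that("empty cohorts yield zeroed reports, not errors", {
  qc <- apply_qc(data.frame(id = integer(), sex = character(),
                            birth_weight_kg = numeric()),
                 data.frame(id = integer(), exam_index = integer(),
                            age_months = numeric(), height_cm = numeric(),
                            weight_kg = numeric()))
  expect_equal(qc$report$n_input, 0)
  expect_equal(qc$report$n_included, 0)
})
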