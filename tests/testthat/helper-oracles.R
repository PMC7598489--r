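# Independent brute-force oracles. These deliberately re-implement the rules
# as plain per-subject loops, sharing no code with the package internals.

# Sequential validity re-scan for one subject: heights/weights are length-7
# vectors with NA for missing exams.
oracle_validate_subject <- function(h, w, bw, strict = TRUE) {
  valid <- logical(7)
  last_h <- NA_real_
  last_w <- NA_real_
  for (j in 1:7) {
    if (is.na(h[j]) || is.na(w[j])) next
    if (h[j] < 25) next
    if (w[j] < bw) next
    if (!is.na(last_h)) {
      if (strict && !(h[j] > last_h && w[j] > last_w)) next
      if (!strict && !(h[j] >= last_h && w[j] >= last_w)) next
    }
    valid[j] <- TRUE
    last_h <- h[j]
    last_w <- w[j]
  }
  valid
}

# Exclusion accounting recomputed from the raw tables, one subject at a time.
oracle_qc_counts <- function(subjects, exams, min_valid = 5) {
  n_bw <- 0L; n_few <- 0L; n_in <- 0L
  for (i in seq_len(nrow(subjects))) {
    bw <- subjects$birth_weight_kg[i]
    if (!is.finite(bw) || bw < 0.5 || bw > 5.0) {
      n_bw <- n_bw + 1L
      next
    }
    rows <- exams[exams$id == subjects$id[i], ]
    h <- rep(NA_real_, 7); w <- rep(NA_real_, 7)
    h[rows$exam_index] <- rows$height_cm
    w[rows$exam_index] <- rows$weight_kg
    if (sum(oracle_validate_subject(h, w, bw)) >= min_valid) {
      n_in <- n_in + 1L
    } else {
      n_few <- n_few + 1L
    }
  }
  c(birth_weight = n_bw, too_few = n_few, included = n_in)
}

# Minimum-BMI scan over one subject's valid exams (length-7 BMI vector, NA
# where invalid/missing); returns NA when exam VII is unavailable.
oracle_nadir <- function(bmi7) {
  if (is.na(bmi7[7])) return(NA_integer_)
  best <- NA_integer_
  for (j in 1:7) {
    if (is.na(bmi7[j])) next
    if (is.na(best) || bmi7[j] < bmi7[best]) best <- j
  }
  best
}

# Textbook Pearson statistic by explicit double loop.
oracle_chisq <- function(O) {
  n <- sum(O)
  stat <- 0
  for (i in seq_len(nrow(O))) {
    for (j in seq_len(ncol(O))) {
      e <- sum(O[i, ]) * sum(O[, j]) / n
      stat <- stat + (O[i, j] - e)^2 / e
    }
  }
  stat
}

# Convenience: simulate, QC and return the clean cohort (plus intermediates).
make_clean <- function(n = 500, seed = 1, ...) {
  co <- generate_cohort(sim_config(n_subjects = n, seed = seed, ...))
  qc <- apply_qc(co$subjects, co$exams)
  list(cohort = co, qc = qc, clean = qc_clean(qc))
}

with_seed_for_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Zero-noise, zero-corruption configuration: the generated records are clean
# by construction.
noise_free_config <- function(n, seed) {
  sim_config(n_subjects = n, seed = seed,
             noise_height_sd = 0, noise_weight_sd = 0,
             p_miss = 0, p_shrink = 0, p_bw_out = 0)
}
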