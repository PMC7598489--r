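#' Birth-weight class
#'
#' Partitions the plausible birth-weight interval into very low (0.5-1.5 kg,
#' both ends closed), low (>1.5-2.5 kg) and non-low (>2.5-5.0 kg) birth
#' weight.
#'
#' @param w0 numeric vector of birth weights in kg, all within \[0.5, 5.0\]
#'   (out-of-range values should already have been removed by QC).
#' @return factor with levels `VLBW`, `LBW`, `non_LBW`.
#' @export
classify_birth_weight <- function(w0) {
  if (any(!is.finite(w0)) || any(w0 < 0.5 | w0 > 5.0)) {
    stop("birth weight outside [0.5, 5.0] kg; run QC first", call. = FALSE)
  }
  out <- rep("non_LBW", length(w0))
  out[w0 <= 2.5] <- "LBW"
  out[w0 <= 1.5] <- "VLBW"
  factor(out, levels = BW_LEVELS)
}

#' Rapid-weight-gain status in early infancy
#'
#' A child is a rapid gainer when the weight gained between birth and the
#' first exam (about 5 months) is at least `threshold` kg. The default
#' 5.1 kg is the gain that moves a boy born at the national median birth
#' weight up 0.67 weight-for-age z-scores — the conventional
#' centile-crossing criterion; see [derive_rwg_threshold()].
#'
#' @param w0 birth weight (kg).
#' @param w_exam1 weight at the first exam (kg); must be `>= w0` for
#'   non-missing entries (QC guarantees this for valid records).
#' @param threshold gain threshold in kg (boundary inclusive).
#' @return data frame `delta_kg`, `rapid`; `NA` rows propagate.
#' @export
classify_rwg <- function(w0, w_exam1, threshold = 5.1) {
  cmp <- !is.na(w0) & !is.na(w_exam1)
  if (any(w_exam1[cmp] < w0[cmp])) {
    stop("weight at exam I below birth weight: invalid record", call. = FALSE)
  }
  delta <- w_exam1 - w0
  out <- data.frame(delta_kg = delta, rapid = delta >= threshold)
  attr(out, "threshold") <- threshold
  out
}

#' Derive a rapid-weight-gain threshold from a growth reference
#'
#' Computes the absolute weight gain that carries a child born at the
#' reference median up `z` z-scores by the first exam:
#' `(mean_exam1 + z * sd_exam1) - mean_birth`.
#'
#' @param mean_birth reference mean (median) birth weight, kg.
#' @param mean_exam1 reference mean weight at the first-exam age, kg.
#' @param sd_exam1 reference SD of weight at the first-exam age, kg.
#' @param z z-score displacement defining "rapid" (default 0.67, one centile
#'   band on standard growth charts).
#' @return threshold in kg.
#' @export
derive_rwg_threshold <- function(mean_birth, mean_exam1, sd_exam1, z = 0.67) {
  for (v in list(mean_birth, mean_exam1, sd_exam1)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("reference means/SD must be single finite numbers", call. = FALSE)
    }
  }
  if (sd_exam1 < 0) stop("reference SD must be non-negative", call. = FALSE)
  (mean_exam1 + z * sd_exam1) - mean_birth
}

#' Empirical percentile thresholds
#'
#' Linear-interpolation (type 7) sample quantiles at the requested
#' percentile levels. The convention matters at small n and is therefore
#' fixed and documented rather than configurable per call.
#'
#' @param values numeric sample (NAs dropped); at least 2 finite values.
#' @param probs percentile levels in (0, 100).
#' @return named numeric vector of thresholds, non-decreasing in `probs`.
#' @export
empirical_percentiles <- function(values, probs) {
  x <- values[is.finite(values)]
  if (length(x) < 2L) {
    stop("need at least 2 finite values for percentiles", call. = FALSE)
  }
  if (any(probs <= 0 | probs >= 100)) {
    stop("percentile levels must lie strictly between 0 and 100",
         call. = FALSE)
  }
  q <- quantile(x, probs = probs / 100, type = 7, names = FALSE)
  names(q) <- paste0("P", probs)
  q
}

#' BMI weight-status category
#'
#' Four categories from three percentile thresholds: underweight
#' (`BMI < P5`), normal (`P5 <= BMI < P85`), overweight
#' (`P85 <= BMI < P95`), obese (`BMI >= P95`).
#'
#' @param bmi numeric vector of BMI values (kg/m^2).
#' @param thresholds numeric length-3 vector `c(P5, P85, P95)`,
#'   non-decreasing.
#' @return ordered factor underweight < normal < overweight < obese.
#' @export
classify_bmi_status <- function(bmi, thresholds) {
  if (length(thresholds) != 3L || is.unsorted(thresholds)) {
    stop("thresholds must be non-decreasing c(P5, P85, P95)", call. = FALSE)
  }
  out <- rep(NA_character_, length(bmi))
  ok <- !is.na(bmi)
  out[ok] <- "underweight"
  out[ok & bmi >= thresholds[1]] <- "normal"
  out[ok & bmi >= thresholds[2]] <- "overweight"
  out[ok & bmi >= thresholds[3]] <- "obese"
  factor(out, levels = BMI_STATUS_LEVELS, ordered = TRUE)
}

#' Subject-level subgroup table
#'
#' Assembles the per-subject subgroup labels used by the analytic layer:
#' birth-weight class, rapid-weight-gain status (birth to exam I; `NA` when
#' exam I is invalid), BMI at the status exam (exam VI by default) and the
#' corresponding weight-status category. Status thresholds are within-cohort
#' empirical percentiles, stratified by sex by default; an external
#' reference table `data.frame(sex, percentile, bmi)` may be supplied
#' instead.
#'
#' @param clean a `"clean_cohort"`.
#' @param rwg_threshold rapid-gain threshold, kg.
#' @param status_exam exam index at which weight status is assessed.
#' @param by_sex stratify percentile thresholds by sex.
#' @param reference optional threshold table with columns `sex`
#'   (`"male"`/`"female"`/`"all"`), `percentile` (5, 85, 95) and `bmi`.
#' @return data frame `id`, `sex`, `bw_class`, `delta_w_kg`, `rwg`,
#'   `bmi_status_exam`, `bmi_status`; attribute `"thresholds"` holds the
#'   per-stratum cutoffs used.
#' @export
subgroup_table <- function(clean, rwg_threshold = 5.1, status_exam = 6L,
                           by_sex = TRUE, reference = NULL) {
  stopifnot(inherits(clean, "clean_cohort"))
  subj <- clean$subjects
  ex <- clean$exams

  bw_class <- classify_birth_weight(subj$birth_weight_kg)

  e1 <- ex[ex$exam_index == 1L & !is.na(ex$valid) & ex$valid, ]
  w1 <- e1$weight_kg[match(subj$id, e1$id)]
  rwg <- classify_rwg(subj$birth_weight_kg, w1, threshold = rwg_threshold)

  e6 <- ex[ex$exam_index == status_exam & !is.na(ex$valid) & ex$valid, ]
  bmi6 <- e6$bmi[match(subj$id, e6$id)]

  strata <- if (by_sex) subj$sex else rep("all", nrow(subj))
  status <- factor(rep(NA_character_, nrow(subj)),
                   levels = BMI_STATUS_LEVELS, ordered = TRUE)
  thresholds <- list()
  for (s in unique(strata)) {
    sel <- strata == s
    thr <- if (is.null(reference)) {
      empirical_percentiles(bmi6[sel], c(5, 85, 95))
    } else {
      ref <- reference[reference$sex == s, ]
      setNames(ref$bmi[match(c(5, 85, 95), ref$percentile)],
               c("P5", "P85", "P95"))
    }
    if (anyNA(thr)) stop("reference thresholds incomplete for stratum ", s,
                         call. = FALSE)
    thresholds[[s]] <- thr
    status[sel] <- classify_bmi_status(bmi6[sel], thr)
  }

  out <- data.frame(
    id = subj$id, sex = subj$sex, bw_class = bw_class,
    delta_w_kg = rwg$delta_kg, rwg = rwg$rapid,
    bmi_status_exam = bmi6, bmi_status = status
  )
  attr(out, "thresholds") <- thresholds
  attr(out, "status_exam") <- status_exam
  out
}
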