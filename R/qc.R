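#' Birth-weight plausibility check
#'
#' A recorded birth weight is plausible when it lies in the closed interval
#' 0.5-5.0 kg; values outside it are treated as registry errors or extreme
#' outliers (gestational age is unavailable, so the bounds stand in for
#' viability limits).
#'
#' @param w0 numeric vector of birth weights (kg).
#' @param range closed plausibility interval, kg.
#' @return logical vector; `NA` inputs fail with an error.
#' @export
check_birth_weight <- function(w0, range = c(0.5, 5.0)) {
  if (!is.numeric(w0)) stop("birth weight must be numeric", call. = FALSE)
  if (any(!is.finite(w0))) {
    stop("birth weight contains missing or non-finite values", call. = FALSE)
  }
  w0 >= range[1] & w0 <= range[2]
}

#' Body mass index from height and weight
#'
#' @param height_cm height or length in cm; must be positive.
#' @param weight_kg weight in kg.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0, na.rm = TRUE)) {
    stop("height must be positive", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

INVALID_REASONS <- c("none", "missing", "height_below_min",
                     "weight_below_birth", "height_not_increased",
                     "weight_not_increased")

#' Sequential validity screen for one child's exam sequence
#'
#' Scans the scheduled exams in order and marks each as valid or invalid.
#' An exam is valid when both measurements are present, height is at least
#' `min_height` cm, weight is at least the birth weight, and both exceed the
#' values at the most recent previously *valid* exam (strictly, by default).
#' When no prior valid exam exists — at exam I, or after a run of invalid
#' exams — the floors themselves (25 cm, birth weight, both inclusive) act as
#' the baseline. Invalid exams never become the comparison baseline, so one
#' corrupted record cannot poison the rest of the sequence.
#'
#' `invalid_reason` records the first failing rule in the fixed order:
#' missing, height_below_min, weight_below_birth, height_not_increased,
#' weight_not_increased.
#'
#' @param exams data frame with columns `exam_index`, `height_cm`,
#'   `weight_kg` (rows for missing exams may be absent); `exam_index` must be
#'   sorted and unique.
#' @param birth_weight the child's birth weight (kg).
#' @param n_exams number of scheduled exams.
#' @param min_height minimum plausible height/length, cm.
#' @param strict if `TRUE` (default) "increased" means strictly greater;
#'   if `FALSE` ties count as increased.
#' @return data frame with one row per scheduled exam: `exam_index`,
#'   `height_cm`, `weight_kg`, `valid`, `invalid_reason`.
#' @export
validate_sequence <- function(exams, birth_weight, n_exams = 7L,
                              min_height = 25, strict = TRUE) {
  ei <- exams$exam_index
  if (is.unsorted(ei, strictly = TRUE)) {
    stop("exam indices must be sorted and unique", call. = FALSE)
  }
  if (any(ei < 1L | ei > n_exams)) {
    stop("exam_index out of range", call. = FALSE)
  }
  h <- rep(NA_real_, n_exams); h[ei] <- exams$height_cm
  w <- rep(NA_real_, n_exams); w[ei] <- exams$weight_kg
  res <- validate_matrix(matrix(h, 1), matrix(w, 1), birth_weight,
                         min_height = min_height, strict = strict)
  data.frame(
    exam_index = seq_len(n_exams),
    height_cm = h, weight_kg = w,
    valid = res$valid[1, ],
    invalid_reason = res$reason[1, ],
    stringsAsFactors = FALSE
  )
}

# Core sequential screen, vectorised over subjects (rows) with one pass per
# scheduled exam (columns). Returns validity and first-failure reason.
validate_matrix <- function(H, W, bw, min_height = 25, strict = TRUE) {
  n <- nrow(H); k <- ncol(H)
  gt <- if (strict) `>` else `>=`
  valid <- matrix(FALSE, n, k)
  reason <- matrix("none", n, k)
  prev_h <- rep(NA_real_, n)
  prev_w <- rep(NA_real_, n)
  for (j in seq_len(k)) {
    h <- H[, j]; w <- W[, j]
    present <- !is.na(h) & !is.na(w)
    h_floor <- present & h >= min_height
    w_floor <- present & w >= bw
    has_prev <- !is.na(prev_h)
    h_inc <- present & (!has_prev | gt(h, ifelse(has_prev, prev_h, -Inf)))
    w_inc <- present & (!has_prev | gt(w, ifelse(has_prev, prev_w, -Inf)))
    ok <- present & h_floor & w_floor & h_inc & w_inc
    r <- rep("none", n)
    r[!w_inc] <- "weight_not_increased"
    r[!h_inc] <- "height_not_increased"
    r[!w_floor] <- "weight_below_birth"
    r[!h_floor] <- "height_below_min"
    r[!present] <- "missing"
    r[ok] <- "none"
    valid[, j] <- ok
    reason[, j] <- r
    prev_h[ok] <- h[ok]
    prev_w[ok] <- w[ok]
  }
  list(valid = valid, reason = reason)
}

#' Apply the full quality-control screen to a cohort
#'
#' Excludes subjects with an out-of-range (or missing) birth weight, runs the
#' sequential record screen of [validate_sequence()] on the remainder, and
#' excludes subjects with fewer than `min_valid` valid exams. The report
#' partitions the input exactly: `n_input = n_excluded_birth_weight +
#' n_excluded_too_few_valid + n_included`.
#'
#' @param subjects data frame `id`, `sex`, `birth_weight_kg`.
#' @param exams data frame `id`, `exam_index`, `age_months`, `height_cm`,
#'   `weight_kg`; missing exams absent as rows.
#' @param exam_ages exam schedule (months), used to fill ages of absent rows.
#' @param min_valid minimum number of valid exams for inclusion.
#' @param bw_range birth-weight plausibility interval (kg).
#' @param min_height minimum plausible height (cm).
#' @param strict strict-increase rule, see [validate_sequence()].
#' @return list of class `"qc_result"`:
#'   \describe{
#'     \item{subjects}{input subjects plus `n_valid`, `included`,
#'       `exclusion_reason`}
#'     \item{exams}{one row per subject x scheduled exam with `valid`,
#'       `invalid_reason`, and `bmi` (computed for valid exams)}
#'     \item{report}{a `"qc_report"` with the exclusion accounting}
#'   }
#' @export
apply_qc <- function(subjects, exams, exam_ages = EXAM_AGES,
                     min_valid = 5L, bw_range = c(0.5, 5.0),
                     min_height = 25, strict = TRUE) {
  n <- nrow(subjects)
  k <- length(exam_ages)
  if (n == 0L) {
    return(structure(list(
      subjects = cbind(subjects, n_valid = integer(0), included = logical(0),
                       exclusion_reason = character(0)),
      exams = data.frame(),
      report = new_qc_report(0L, 0L, 0L, 0L, integer(0))
    ), class = "qc_result"))
  }
  if (anyDuplicated(subjects$id)) stop("duplicate subject ids", call. = FALSE)

  bw <- subjects$birth_weight_kg
  bw_ok <- is.finite(bw) & bw >= bw_range[1] & bw <= bw_range[2]

  row <- match(exams$id, subjects$id)
  if (anyNA(row)) stop("exam rows with unknown subject id", call. = FALSE)
  if (anyDuplicated(cbind(row, exams$exam_index))) {
    stop("duplicate (id, exam_index) rows", call. = FALSE)
  }
  if (any(exams$exam_index < 1L | exams$exam_index > k)) {
    stop("exam_index out of range", call. = FALSE)
  }
  H <- matrix(NA_real_, n, k)
  W <- matrix(NA_real_, n, k)
  AGE <- matrix(rep(exam_ages, each = n), n, k)
  pos <- cbind(row, exams$exam_index)
  H[pos] <- exams$height_cm
  W[pos] <- exams$weight_kg
  if (!is.null(exams$age_months)) AGE[pos] <- exams$age_months

  # NA birth weights are excluded below anyway; use -Inf so the screen runs
  scr <- validate_matrix(H, W, ifelse(is.finite(bw), bw, -Inf),
                         min_height = min_height, strict = strict)
  # subjects failing the birth-weight filter are excluded before the record
  # screen; their exam validity is not assessed
  scr$valid[!bw_ok, ] <- NA
  scr$reason[!bw_ok, ] <- NA_character_

  n_valid <- ifelse(bw_ok, rowSums(scr$valid, na.rm = TRUE), NA_integer_)
  included <- bw_ok & !is.na(n_valid) & n_valid >= min_valid
  reason <- rep("none", n)
  reason[!bw_ok] <- "birth_weight_out_of_range"
  reason[bw_ok & !included] <- "fewer_than_5_valid"

  out_subjects <- subjects
  out_subjects$n_valid <- n_valid
  out_subjects$included <- included
  out_subjects$exclusion_reason <- reason

  valid_vec <- as.vector(scr$valid)
  out_exams <- data.frame(
    id = rep(subjects$id, k),
    exam_index = rep(seq_len(k), each = n),
    age_months = as.vector(AGE),
    height_cm = as.vector(H),
    weight_kg = as.vector(W),
    valid = valid_vec,
    invalid_reason = as.vector(scr$reason),
    stringsAsFactors = FALSE
  )
  out_exams <- out_exams[order(out_exams$id, out_exams$exam_index), ]
  rownames(out_exams) <- NULL
  out_exams$bmi <- NA_real_
  ok <- !is.na(out_exams$valid) & out_exams$valid
  out_exams$bmi[ok] <- compute_bmi(out_exams$height_cm[ok],
                                   out_exams$weight_kg[ok])

  reason_tab <- table(factor(
    scr$reason[bw_ok, , drop = FALSE][scr$reason[bw_ok, , drop = FALSE] != "none"],
    levels = setdiff(INVALID_REASONS, "none")
  ))
  report <- new_qc_report(
    n_input = n,
    n_excluded_birth_weight = sum(!bw_ok),
    n_excluded_too_few_valid = sum(bw_ok & !included),
    n_included = sum(included),
    invalid_records = as.integer(reason_tab)
  )
  names(report$invalid_records) <- names(reason_tab)

  structure(list(subjects = out_subjects, exams = out_exams, report = report),
            class = "qc_result")
}

new_qc_report <- function(n_input, n_excluded_birth_weight,
                          n_excluded_too_few_valid, n_included,
                          invalid_records) {
  structure(list(
    n_input = n_input,
    n_excluded_birth_weight = n_excluded_birth_weight,
    n_excluded_too_few_valid = n_excluded_too_few_valid,
    n_included = n_included,
    invalid_records = invalid_records
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Quality-control report\n")
  cat(sprintf("  subjects in:                 %d\n", x$n_input))
  cat(sprintf("  excluded, birth weight:      %d\n", x$n_excluded_birth_weight))
  cat(sprintf("  excluded, <min valid exams:  %d\n", x$n_excluded_too_few_valid))
  cat(sprintf("  included:                    %d\n", x$n_included))
  if (length(x$invalid_records)) {
    cat("  invalid records by reason:\n")
    for (r in names(x$invalid_records)) {
      cat(sprintf("    %-22s %d\n", r, x$invalid_records[[r]]))
    }
  }
  invisible(x)
}

#' Extract the clean (included) cohort from a QC result
#'
#' @param qc a `"qc_result"` from [apply_qc()].
#' @return list of class `"clean_cohort"` with `subjects` (included only) and
#'   `exams` (their scheduled exams with validity flags and BMI).
#' @export
qc_clean <- function(qc) {
  stopifnot(inherits(qc, "qc_result"))
  subj <- qc$subjects[qc$subjects$included, , drop = FALSE]
  rownames(subj) <- NULL
  ex <- qc$exams[qc$exams$id %in% subj$id, , drop = FALSE]
  rownames(ex) <- NULL
  structure(list(subjects = subj, exams = ex), class = "clean_cohort")
}
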