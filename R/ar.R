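#' Locate the BMI nadir of one child
#'
#' The timing of adiposity rebound is approximated by the exam at which the
#' lowest BMI occurred. Ties are broken to the earliest tying exam by default
#' (flagged, and switchable to latest for sensitivity analysis). The nadir is
#' *unidentifiable* when the final scheduled exam is missing or invalid:
#' without the last observation a subsequent rebound cannot be confirmed, so
#' the subject is treated as missing for rebound-timing analyses.
#'
#' @param exams one child's scheduled exams: data frame with `exam_index`,
#'   `valid`, and `bmi` (or `height_cm`/`weight_kg` from which BMI is
#'   computed).
#' @param n_exams number of scheduled exams.
#' @param tie `"earliest"` or `"latest"` tying exam.
#' @return list of class `"nadir_result"`: `nadir_exam` (integer or `NA`),
#'   `nadir_bmi`, `tie` flag, `identifiable` flag.
#' @export
find_nadir <- function(exams, n_exams = 7L, tie = c("earliest", "latest")) {
  tie <- match.arg(tie)
  if (is.null(exams$valid)) {
    stop("exams must carry validity flags (run apply_qc first)", call. = FALSE)
  }
  bmi <- exams$bmi
  if (is.null(bmi)) bmi <- compute_bmi(exams$height_cm, exams$weight_kg)
  v <- rep(NA_real_, n_exams)
  ok <- !is.na(exams$valid) & exams$valid
  v[exams$exam_index[ok]] <- bmi[ok]
  if (sum(!is.na(v)) < 1L) stop("no valid exams", call. = FALSE)

  identifiable <- !is.na(v[n_exams])
  if (!identifiable) {
    return(structure(list(nadir_exam = NA_integer_, nadir_bmi = NA_real_,
                          tie = FALSE, identifiable = FALSE),
                     class = "nadir_result"))
  }
  mn <- min(v, na.rm = TRUE)
  at <- which(!is.na(v) & v == mn)
  structure(list(
    nadir_exam = if (tie == "earliest") at[1] else at[length(at)],
    nadir_bmi = mn,
    tie = length(at) > 1L,
    identifiable = TRUE
  ), class = "nadir_result")
}

#' Classify adiposity-rebound timing from the nadir exam
#'
#' Maps the nadir exam to the three timing classes: exams I-V (up to 45
#' months) are *very early*, exam VI (57 months) is *early*, and exam VII
#' (69 months, i.e. no rebound observed before the last exam) is
#' *moderate-to-late*. Unidentifiable nadirs map to *unclassified*.
#'
#' @param nadir_exam integer vector of nadir exam indices (`NA` =
#'   unidentifiable), or a single `"nadir_result"`.
#' @param n_exams number of scheduled exams.
#' @return factor with levels very_early, early, moderate_to_late,
#'   unclassified.
#' @export
classify_ar <- function(nadir_exam, n_exams = 7L) {
  if (inherits(nadir_exam, "nadir_result")) nadir_exam <- nadir_exam$nadir_exam
  out <- rep("unclassified", length(nadir_exam))
  out[!is.na(nadir_exam) & nadir_exam <= n_exams - 2L] <- "very_early"
  out[!is.na(nadir_exam) & nadir_exam == n_exams - 1L] <- "early"
  out[!is.na(nadir_exam) & nadir_exam == n_exams] <- "moderate_to_late"
  factor(out, levels = AR_LEVELS)
}

#' Nadir detection and rebound-timing classification for a whole cohort
#'
#' Vectorised equivalent of [find_nadir()] + [classify_ar()] over every
#' included subject of a clean cohort.
#'
#' @param clean a `"clean_cohort"` from [qc_clean()].
#' @param n_exams number of scheduled exams.
#' @param tie tie-breaking rule, see [find_nadir()].
#' @return data frame: `id`, `nadir_exam`, `nadir_bmi`, `tie`, `ar_class`.
#' @export
classify_cohort <- function(clean, n_exams = 7L,
                            tie = c("earliest", "latest")) {
  tie <- match.arg(tie)
  stopifnot(inherits(clean, "clean_cohort"))
  subj <- clean$subjects
  ex <- clean$exams
  n <- nrow(subj)
  M <- matrix(NA_real_, n, n_exams)
  ok <- !is.na(ex$valid) & ex$valid
  M[cbind(match(ex$id[ok], subj$id), ex$exam_index[ok])] <- ex$bmi[ok]

  identifiable <- !is.na(M[, n_exams])
  Mi <- M
  Mi[is.na(Mi)] <- Inf
  mn <- do.call(pmin, as.data.frame(Mi))
  is_min <- Mi == mn
  first_at <- max.col(is_min, ties.method = "first")
  last_at <- max.col(is_min, ties.method = "last")
  at <- if (tie == "earliest") first_at else last_at

  out <- data.frame(
    id = subj$id,
    nadir_exam = ifelse(identifiable, at, NA_integer_),
    nadir_bmi = ifelse(identifiable, mn, NA_real_),
    tie = identifiable & (first_at != last_at)
  )
  out$ar_class <- classify_ar(out$nadir_exam, n_exams)
  out
}

#' Prevalence of rebound timing by exam
#'
#' Tabulates, over classified (identifiable) subjects only, the count and
#' percentage of children whose BMI nadir falls at each scheduled exam,
#' overall and by sex, together with cumulative percentages.
#'
#' @param classification output of [classify_cohort()].
#' @param subjects subject table carrying `id` and `sex`.
#' @param n_exams number of scheduled exams.
#' @param exam_ages schedule ages in months (reporting only).
#' @return data frame with one row per exam: counts, percentages and
#'   cumulative percentages for total / male / female; attribute
#'   `n_classified` carries the denominators.
#' @export
prevalence <- function(classification, subjects, n_exams = 7L,
                       exam_ages = EXAM_AGES) {
  cls <- classification[!is.na(classification$nadir_exam), , drop = FALSE]
  if (nrow(cls) == 0L) {
    stop("no classified subjects: prevalence table undefined", call. = FALSE)
  }
  sex <- subjects$sex[match(cls$id, subjects$id)]
  lev <- seq_len(n_exams)
  tot <- tabulate(cls$nadir_exam, n_exams)
  male <- tabulate(cls$nadir_exam[sex == "male"], n_exams)
  female <- tabulate(cls$nadir_exam[sex == "female"], n_exams)
  pct <- function(x) if (sum(x) > 0) 100 * x / sum(x) else rep(0, length(x))
  out <- data.frame(
    exam_index = lev,
    age_months = exam_ages[lev],
    n_total = tot, pct_total = pct(tot), cum_pct_total = cumsum(pct(tot)),
    n_male = male, pct_male = pct(male), cum_pct_male = cumsum(pct(male)),
    n_female = female, pct_female = pct(female),
    cum_pct_female = cumsum(pct(female))
  )
  attr(out, "n_classified") <- c(total = sum(tot), male = sum(male),
                                 female = sum(female))
  out
}

#' Prevalence of the three rebound-timing classes
#'
#' @param ar_class factor of per-subject classes (unclassified subjects are
#'   dropped from the denominator).
#' @return data frame `ar_class`, `n`, `pct` over classified subjects.
#' @export
class_prevalence <- function(ar_class) {
  cls <- ar_class[ar_class != "unclassified"]
  cls <- factor(cls, levels = setdiff(AR_LEVELS, "unclassified"))
  if (length(cls) == 0L) stop("no classified subjects", call. = FALSE)
  tab <- table(cls)
  data.frame(
    ar_class = names(tab),
    n = as.integer(tab),
    pct = 100 * as.integer(tab) / length(cls)
  )
}

#' Indicator of adiposity rebound before the sixth exam (57 months)
#'
#' The binary outcome used for odds-ratio analyses: `TRUE` when the rebound
#' class is very early or early (nadir at exam VI or sooner), `FALSE` for
#' moderate-to-late, `NA` for unclassified.
#'
#' @param ar_class factor from [classify_ar()].
#' @return logical vector.
#' @export
ar_before_57 <- function(ar_class) {
  out <- ar_class %in% c("very_early", "early")
  out[ar_class == "unclassified"] <- NA
  out
}
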