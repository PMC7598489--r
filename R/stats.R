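#' Cross-tabulate two subject-level factors
#'
#' Builds an exact contingency table of two factors over the subjects for
#' which both are defined; subjects with a missing level in either factor are
#' excluded and counted.
#'
#' @param data data frame of subject-level variables.
#' @param row_factor,col_factor column names in `data`.
#' @return object of class `"contingency_table"`: `counts` (integer matrix
#'   with level dimnames), `row_margin`, `col_margin`, `n`, `n_excluded`,
#'   and the factor names.
#' @export
crosstab <- function(data, row_factor, col_factor) {
  for (f in c(row_factor, col_factor)) {
    if (!f %in% names(data)) stop("unknown factor: ", f, call. = FALSE)
  }
  r <- data[[row_factor]]
  c_ <- data[[col_factor]]
  keep <- !is.na(r) & !is.na(c_)
  counts <- table(r[keep], c_[keep], dnn = c(row_factor, col_factor))
  counts <- unclass(counts)
  storage.mode(counts) <- "integer"
  structure(list(
    counts = counts,
    row_margin = rowSums(counts),
    col_margin = colSums(counts),
    n = sum(counts),
    n_excluded = sum(!keep),
    row_factor = row_factor,
    col_factor = col_factor
  ), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table: %s x %s (n = %d, excluded = %d)\n",
              x$row_factor, x$col_factor, x$n, x$n_excluded))
  print(x$counts)
  invisible(x)
}

as_count_matrix <- function(x) {
  if (inherits(x, "contingency_table")) x$counts
  else if (is.matrix(x)) x
  else stop("expected a contingency_table or counts matrix", call. = FALSE)
}

#' Pearson chi-square test of independence
#'
#' Classical Pearson statistic \eqn{\sum (O-E)^2/E} with
#' \eqn{df = (R-1)(C-1)}; no continuity correction.
#'
#' @param x a [crosstab()] result or counts matrix.
#' @return list `statistic`, `df`, `p.value`, `expected`.
#' @export
chi_square <- function(x) {
  O <- as_count_matrix(x)
  rm_ <- rowSums(O); cm_ <- colSums(O); n <- sum(O)
  if (any(rm_ == 0) || any(cm_ == 0) || n == 0) {
    stop("degenerate table: zero margin", call. = FALSE)
  }
  E <- outer(rm_, cm_) / n
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Likelihood-ratio (G) test of independence
#'
#' \eqn{G = 2 \sum O \ln(O/E)} with zero cells contributing zero;
#' \eqn{df = (R-1)(C-1)}.
#'
#' @param x a [crosstab()] result or counts matrix.
#' @return list `statistic`, `df`, `p.value`, `expected`.
#' @export
likelihood_ratio_test <- function(x) {
  O <- as_count_matrix(x)
  rm_ <- rowSums(O); cm_ <- colSums(O); n <- sum(O)
  if (any(rm_ == 0) || any(cm_ == 0) || n == 0) {
    stop("degenerate table: zero margin", call. = FALSE)
  }
  E <- outer(rm_, cm_) / n
  terms <- ifelse(O > 0, O * log(O / E), 0)
  stat <- 2 * sum(terms)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Crude odds ratio with Wald confidence interval
#'
#' For a 2x2 table `[[a, b], [c, d]]` (rows = exposure, columns = outcome),
#' `OR = ad/bc` with the Wald interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param x 2x2 counts matrix or [crosstab()] result.
#' @param conf confidence level.
#' @param haldane add 0.5 to every cell (only needed with zero cells; off by
#'   default).
#' @return data frame of class `"or_result"`: `or`, `ci_low`, `ci_high`,
#'   `p.value`, `method`.
#' @export
crude_or <- function(x, conf = 0.95, haldane = FALSE) {
  O <- as_count_matrix(x)
  if (!all(dim(O) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  O <- O + if (haldane) 0.5 else 0
  if (any(O == 0)) {
    stop("zero cell: odds ratio undefined (set haldane = TRUE to correct)",
         call. = FALSE)
  }
  a <- O[1, 1]; b <- O[1, 2]; c_ <- O[2, 1]; d <- O[2, 2]
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- 2 * pnorm(-abs(log(or) / se))
  structure(data.frame(
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    p.value = p,
    method = "crude"
  ), class = c("or_result", "data.frame"))
}

#' Logistic regression odds ratios with Wald intervals
#'
#' Maximum-likelihood binary logistic fit (iteratively reweighted least
#' squares, convergence tolerance 1e-8, at most 100 iterations) of a binary
#' outcome on a categorical exposure plus optional numeric adjustment
#' covariates. Exponentiated coefficients are odds ratios against the
#' exposure's reference (first) level. Complete or quasi-complete separation
#' is flagged rather than silently reported.
#'
#' @param data data frame holding the variables.
#' @param outcome name of a logical/0-1 column.
#' @param exposure name of a factor/character column; first level is the
#'   reference.
#' @param covariates character vector of numeric adjustment columns.
#' @param conf confidence level.
#' @return data frame of class `"or_result"` with one row per non-reference
#'   exposure level: `level`, `reference`, `or`, `ci_low`, `ci_high`,
#'   `p.value`, `adjusted_for`, `flagged`.
#' @export
fit_logistic <- function(data, outcome, exposure, covariates = character(),
                         conf = 0.95) {
  for (v in c(outcome, exposure, covariates)) {
    if (!v %in% names(data)) stop("unknown column: ", v, call. = FALSE)
  }
  d <- data[, c(outcome, exposure, covariates), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  y <- d[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("outcome is constant", call. = FALSE)
  d[[outcome]] <- y
  if (!is.factor(d[[exposure]])) d[[exposure]] <- factor(d[[exposure]])
  # force treatment contrasts: an ordered factor would fit polynomial terms
  # instead of odds ratios against a reference level
  d[[exposure]] <- factor(d[[exposure]], levels = levels(d[[exposure]]),
                          ordered = FALSE)
  d[[exposure]] <- droplevels(d[[exposure]])
  if (nlevels(d[[exposure]]) < 2L) {
    stop("exposure has a single level", call. = FALSE)
  }

  rhs <- paste(c(sprintf("`%s`", exposure),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fml <- as.formula(sprintf("`%s` ~ %s", outcome, rhs))
  fit <- glm(fml, data = d, family = binomial(),
             control = list(epsilon = 1e-8, maxit = 100))

  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  # separation heuristic: runaway coefficients or exploding standard errors
  flagged <- !fit$converged | abs(cf) > 15 | se > 100

  lev <- levels(d[[exposure]])
  terms <- paste0(sprintf("`%s`", exposure), lev[-1])
  if (!all(terms %in% names(cf))) terms <- paste0(exposure, lev[-1])
  z <- qnorm(1 - (1 - conf) / 2)
  est <- cf[terms]; ese <- se[terms]
  structure(data.frame(
    level = lev[-1],
    reference = lev[1],
    or = exp(est),
    ci_low = exp(est - z * ese),
    ci_high = exp(est + z * ese),
    p.value = 2 * pnorm(-abs(est / ese)),
    adjusted_for = if (length(covariates)) paste(covariates, collapse = "+")
                   else "",
    flagged = unname(flagged[terms]),
    row.names = NULL
  ), class = c("or_result", "data.frame"))
}

#' Empirical BMI percentile curves across the exam schedule
#'
#' For each scheduled exam, computes the [empirical_percentiles()] of the
#' valid BMIs at that exam, optionally restricted to one sex. The defaults
#' reproduce the 13 standard chart levels. Extreme levels (1st/99th) are
#' meaningless at small n, hence the documented minimum.
#'
#' @param clean a `"clean_cohort"`.
#' @param sex `"male"`, `"female"` or `NULL` for all subjects.
#' @param levels percentile levels in (0, 100).
#' @param min_n minimum valid BMIs required at every exam.
#' @param exam_ages schedule ages (months) for reporting.
#' @return long data frame of class `"percentile_curves"`: `sex`, `level`,
#'   `exam_index`, `age_months`, `bmi`.
#' @export
percentile_curves <- function(clean, sex = NULL,
                              levels = c(1, 3, 5, 10, 15, 25, 50, 75, 85,
                                         90, 95, 97, 99),
                              min_n = 100L, exam_ages = EXAM_AGES) {
  stopifnot(inherits(clean, "clean_cohort"))
  ex <- clean$exams
  if (!is.null(sex)) {
    ids <- clean$subjects$id[clean$subjects$sex == sex]
    ex <- ex[ex$id %in% ids, ]
  }
  ex <- ex[!is.na(ex$valid) & ex$valid, ]
  ns <- tabulate(ex$exam_index, length(exam_ages))
  if (any(ns < min_n)) {
    stop("too few valid BMIs (min ", min_n, ") at exam(s) ",
         paste(which(ns < min_n), collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(exam_ages), function(j) {
    q <- empirical_percentiles(ex$bmi[ex$exam_index == j], levels)
    data.frame(sex = sex %||% "all", level = levels, exam_index = j,
               age_months = exam_ages[j], bmi = unname(q))
  }))
  class(out) <- c("percentile_curves", "data.frame")
  out
}

#' Per-exam sex comparison of BMI
#'
#' Welch (unequal-variance) two-sample t-test of male vs female BMI at each
#' scheduled exam. Exams where either sex is absent are reported with a note
#' instead of a test.
#'
#' @param clean a `"clean_cohort"`.
#' @param exam_ages schedule ages (months).
#' @return data frame: `exam_index`, `age_months`, `n_male`, `n_female`,
#'   `mean_male`, `mean_female`, `t`, `df`, `p.value`, `note`.
#' @export
sex_compare <- function(clean, exam_ages = EXAM_AGES) {
  stopifnot(inherits(clean, "clean_cohort"))
  ex <- clean$exams[!is.na(clean$exams$valid) & clean$exams$valid, ]
  sex <- clean$subjects$sex[match(ex$id, clean$subjects$id)]
  out <- lapply(seq_along(exam_ages), function(j) {
    m <- ex$bmi[ex$exam_index == j & sex == "male"]
    f <- ex$bmi[ex$exam_index == j & sex == "female"]
    row <- data.frame(exam_index = j, age_months = exam_ages[j],
                      n_male = length(m), n_female = length(f),
                      mean_male = mean(m), mean_female = mean(f),
                      t = NA_real_, df = NA_real_, p.value = NA_real_,
                      note = "")
    if (length(m) < 2L || length(f) < 2L) {
      row$note <- "skipped: fewer than 2 observations in one sex"
      return(row)
    }
    vm <- stats::var(m) / length(m)
    vf <- stats::var(f) / length(f)
    tt <- (mean(m) - mean(f)) / sqrt(vm + vf)
    dfw <- (vm + vf)^2 /
      (vm^2 / (length(m) - 1) + vf^2 / (length(f) - 1))
    row$t <- tt
    row$df <- dfw
    row$p.value <- 2 * stats::pt(-abs(tt), dfw)
    row
  })
  do.call(rbind, out)
}
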