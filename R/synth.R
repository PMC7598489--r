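#' Configuration for the synthetic check-up cohort generator
#'
#' Builds and validates the hyper-parameter set that drives
#' [generate_cohort()]. The defaults describe a cohort with the statistical
#' structure the downstream analysis assumes: a per-child BMI curve that peaks
#' in infancy (cohort mean near 17.8 kg/m\eqn{^2} at 5 months), declines to a
#' nadir (mean near 15.9 kg/m\eqn{^2}, nadir age lognormal with median 48
#' months so that a realistic fraction of children rebound only after the last
#' scheduled exam), and rises quadratically afterwards; a Jenss-Bayley height
#' curve; a birth-weight distribution with low/very-low tails; measurement
#' noise; missing exams; and corrupted (shrinking-height or out-of-range
#' birth-weight) records.
#'
#' Each stochastic mechanism (parameter sampling, measurement noise,
#' corruption, optional age jitter) consumes an independent random stream
#' derived from `seed`, so switching one mechanism off does not change the
#' draws of the others.
#'
#' @param n_subjects number of children to simulate.
#' @param seed integer seed; all streams derive from it.
#' @param exam_ages strictly increasing exam schedule in months.
#' @param p_male probability a child is male.
#' @param w0_mean,w0_sd,w0_min,w0_max truncated-normal birth weight (kg).
#' @param b0_mean,b0_sd birth BMI (kg/m^2); truncated per child below the
#'   sampled peak BMI so the infancy peak exists.
#' @param t_peak_range uniform range for the BMI peak age (months).
#' @param b_nadir_mean,b_nadir_sd nadir BMI (kg/m^2).
#' @param peak_gap_mean,peak_gap_sd,peak_gap_min truncated-normal gap between
#'   peak and nadir BMI (kg/m^2); peak BMI = nadir BMI + gap.
#' @param t_nadir_meanlog,t_nadir_sdlog lognormal nadir age (months).
#' @param k_reb_meanlog,k_reb_sdlog lognormal post-nadir rebound curvature
#'   (kg/m^2/month^2).
#' @param height_a_mean,height_a_sd Jenss-Bayley asymptote-intercept A (cm).
#' @param height_b_mean,height_b_sd Jenss-Bayley linear slope (cm/month).
#' @param birth_length_mean,birth_length_sd birth length (cm); the
#'   exponential-term coefficient is C = A - birth length.
#' @param height_d_mean,height_d_sd Jenss-Bayley decay rate (1/month).
#' @param noise_height_sd,noise_weight_sd measurement noise SDs (cm, kg).
#' @param p_miss per-exam probability that a check-up is missing.
#' @param p_shrink per-exam probability of a corrupted height record (height
#'   reduced by Uniform(3, 10) cm, typically creating a non-increasing
#'   sequence).
#' @param p_bw_out per-subject probability that the recorded birth weight is
#'   replaced by a value outside the plausible 0.5-5.0 kg range.
#' @param jitter_ages if `TRUE`, exam ages are drawn uniformly within the
#'   national visit windows instead of fixed at the schedule medians.
#'
#' @return a validated list of class `"sim_config"`.
#' @seealso [generate_cohort()], [sample_growth_params()]
#' @export
sim_config <- function(n_subjects = 1000L,
                       seed = 1L,
                       exam_ages = EXAM_AGES,
                       p_male = 0.5,
                       w0_mean = 3.2, w0_sd = 0.45,
                       w0_min = 0.4, w0_max = 5.5,
                       b0_mean = 13, b0_sd = 1,
                       t_peak_range = c(6, 10),
                       b_nadir_mean = 15.9, b_nadir_sd = 1.3,
                       peak_gap_mean = 2.0, peak_gap_sd = 0.6,
                       peak_gap_min = 0.3,
                       t_nadir_meanlog = log(48), t_nadir_sdlog = 0.35,
                       k_reb_meanlog = log(0.0015), k_reb_sdlog = 0.5,
                       height_a_mean = 82, height_a_sd = 3,
                       height_b_mean = 0.55, height_b_sd = 0.05,
                       birth_length_mean = 50, birth_length_sd = 2,
                       height_d_mean = 0.065, height_d_sd = 0.01,
                       noise_height_sd = 0.5, noise_weight_sd = 0.15,
                       p_miss = 0.05, p_shrink = 0.01, p_bw_out = 0.002,
                       jitter_ages = FALSE) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), seed = seed,
    exam_ages = as.numeric(exam_ages), p_male = p_male,
    w0_mean = w0_mean, w0_sd = w0_sd, w0_min = w0_min, w0_max = w0_max,
    b0_mean = b0_mean, b0_sd = b0_sd,
    t_peak_range = as.numeric(t_peak_range),
    b_nadir_mean = b_nadir_mean, b_nadir_sd = b_nadir_sd,
    peak_gap_mean = peak_gap_mean, peak_gap_sd = peak_gap_sd,
    peak_gap_min = peak_gap_min,
    t_nadir_meanlog = t_nadir_meanlog, t_nadir_sdlog = t_nadir_sdlog,
    k_reb_meanlog = k_reb_meanlog, k_reb_sdlog = k_reb_sdlog,
    height_a_mean = height_a_mean, height_a_sd = height_a_sd,
    height_b_mean = height_b_mean, height_b_sd = height_b_sd,
    birth_length_mean = birth_length_mean, birth_length_sd = birth_length_sd,
    height_d_mean = height_d_mean, height_d_sd = height_d_sd,
    noise_height_sd = noise_height_sd, noise_weight_sd = noise_weight_sd,
    p_miss = p_miss, p_shrink = p_shrink, p_bw_out = p_bw_out,
    jitter_ages = isTRUE(jitter_ages)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fail <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 1L) fail("n_subjects must be >= 1")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed)) {
    fail("seed must be a single finite number")
  }
  if (length(cfg$exam_ages) < 1L || any(diff(cfg$exam_ages) <= 0)) {
    fail("exam_ages must be strictly increasing")
  }
  for (p in c("p_male", "p_miss", "p_shrink", "p_bw_out")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      fail(sprintf("%s must be a probability in [0, 1]", p))
    }
  }
  sds <- c("w0_sd", "b0_sd", "b_nadir_sd", "peak_gap_sd", "height_a_sd",
           "height_b_sd", "birth_length_sd", "height_d_sd",
           "noise_height_sd", "noise_weight_sd", "t_nadir_sdlog",
           "k_reb_sdlog")
  for (p in sds) {
    if (!is.numeric(cfg[[p]]) || is.na(cfg[[p]]) || cfg[[p]] < 0) {
      fail(sprintf("%s must be a non-negative SD", p))
    }
  }
  if (cfg$w0_min >= cfg$w0_max) fail("empty birth-weight truncation interval")
  if (cfg$w0_min <= 0) fail("w0_min must be positive")
  if (length(cfg$t_peak_range) != 2L || cfg$t_peak_range[1] > cfg$t_peak_range[2]) {
    fail("t_peak_range must be an ordered pair")
  }
  if (cfg$t_peak_range[1] <= 0) fail("t_peak_range must be positive")
  if (cfg$peak_gap_min <= 0) fail("peak_gap_min must be positive")
  structure(cfg, class = "sim_config")
}

#' Sample per-child growth-curve parameters
#'
#' Draws `n` parameter sets from the truncated distributions in `config`.
#' Cross-parameter invariants are enforced by per-child truncation: the nadir
#' age exceeds the peak age, peak BMI exceeds both birth and nadir BMI, and
#' birth length stays below the height intercept so birth length is positive
#' and the height curve is monotone increasing.
#'
#' @param config a [sim_config()].
#' @param n number of parameter sets to draw.
#' @return data frame with one row per child: `sex`, `w0`, `b0`, `b_peak`,
#'   `t_peak`, `b_nadir`, `t_nadir`, `k_reb`, `height_a`, `height_b`,
#'   `height_c`, `height_d`.
#' @export
sample_growth_params <- function(config, n = config$n_subjects) {
  stopifnot(inherits(config, "sim_config"))
  sex <- ifelse(runif(n) < config$p_male, "male", "female")
  w0 <- rtnorm(n, config$w0_mean, config$w0_sd, config$w0_min, config$w0_max)
  b_nadir <- rtnorm(n, config$b_nadir_mean, config$b_nadir_sd, lower = 8)
  gap <- rtnorm(n, config$peak_gap_mean, config$peak_gap_sd,
                lower = config$peak_gap_min)
  b_peak <- b_nadir + gap
  # birth BMI capped just below the peak so the infancy peak is genuine
  b0 <- rtnorm(n, config$b0_mean, config$b0_sd, upper = b_peak - 0.1)
  t_peak <- if (diff(config$t_peak_range) == 0) {
    rep_len(config$t_peak_range[1], n)
  } else {
    runif(n, config$t_peak_range[1], config$t_peak_range[2])
  }
  t_nadir <- rtlnorm(n, config$t_nadir_meanlog, config$t_nadir_sdlog,
                     lower = t_peak + 1)
  k_reb <- rtlnorm(n, config$k_reb_meanlog, config$k_reb_sdlog)
  height_a <- rtnorm(n, config$height_a_mean, config$height_a_sd, lower = 65)
  birth_len <- rtnorm(n, config$birth_length_mean, config$birth_length_sd,
                      lower = 35, upper = height_a - 10)
  data.frame(
    sex = sex, w0 = w0, b0 = b0, b_peak = b_peak, t_peak = t_peak,
    b_nadir = b_nadir, t_nadir = t_nadir, k_reb = k_reb,
    height_a = height_a,
    height_b = rtnorm(n, config$height_b_mean, config$height_b_sd, lower = 0.2),
    height_c = height_a - birth_len,
    height_d = rtnorm(n, config$height_d_mean, config$height_d_sd, lower = 0.02),
    stringsAsFactors = FALSE
  )
}

#' Evaluate the noise-free growth curves of one child
#'
#' The BMI trajectory is a piecewise-quadratic curve with an infancy peak at
#' `t_peak` and a single interior minimum at `t_nadir`:
#' \deqn{BMI(t) = B_{peak} - (B_{peak} - B_0)\,((t_{peak}-t)/t_{peak})^2,\quad t < t_{peak}}
#' \deqn{BMI(t) = B_R + (B_{peak} - B_R)\,((t_R-t)/(t_R-t_{peak}))^2,\quad t_{peak} \le t < t_R}
#' \deqn{BMI(t) = B_R + k\,(t-t_R)^2,\quad t \ge t_R}
#' Height follows the Jenss-Bayley form
#' \eqn{h(t) = A + Bt - C e^{-Dt}} and weight is implied,
#' \eqn{w(t) = BMI(t) (h(t)/100)^2}.
#'
#' @param params a single parameter set: one row of
#'   [sample_growth_params()] output (or an equivalent list).
#' @param t vector of ages in months, all `>= 0`.
#' @return data frame with columns `age_months`, `bmi`, `height_cm`,
#'   `weight_kg`.
#' @export
eval_growth_curves <- function(params, t) {
  p <- as.list(params)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("ages must be finite and non-negative", call. = FALSE)
  }
  bmi <- bmi_curve(t, p$b0, p$b_peak, p$t_peak, p$b_nadir, p$t_nadir, p$k_reb)
  height <- height_curve(t, p$height_a, p$height_b, p$height_c, p$height_d)
  data.frame(
    age_months = t, bmi = bmi, height_cm = height,
    weight_kg = bmi * (height / 100)^2
  )
}

# Vectorised over children and ages; all params may be vectors recycled
# against t (used with scalar t and vector params by generate_cohort).
bmi_curve <- function(t, b0, b_peak, t_peak, b_nadir, t_nadir, k_reb) {
  pre <- t < t_peak
  mid <- !pre & t < t_nadir
  out <- b_nadir + k_reb * (t - t_nadir)^2
  if (any(mid)) {
    frac <- (t_nadir - t) / (t_nadir - t_peak)
    out[mid] <- (b_nadir + (b_peak - b_nadir) * frac^2)[mid]
  }
  if (any(pre)) {
    frac <- (t_peak - t) / t_peak
    out[pre] <- (b_peak - (b_peak - b0) * frac^2)[pre]
  }
  out
}

height_curve <- function(t, a, b, c, d) a + b * t - c * exp(-d * t)

#' Generate a synthetic check-up cohort with ground truth
#'
#' Simulates `config$n_subjects` children: growth parameters are sampled,
#' the noise-free curves are evaluated at the exam schedule, Gaussian
#' measurement noise is added, and corruptions are applied in a documented
#' order (noise, then height shrinking, then exam drop-out, then birth-weight
#' replacement). The truth table logs every corruption together with the
#' noise-free argmin exam, enabling exact recovery checks downstream.
#'
#' @param config a [sim_config()].
#' @return list of class `"synth_cohort"` with elements
#'   \describe{
#'     \item{subjects}{`id`, `sex`, `birth_weight_kg`}
#'     \item{exams}{`id`, `exam_index`, `age_months`, `height_cm`,
#'       `weight_kg`; missing exams are absent as rows}
#'     \item{truth}{per-child parameters, `true_nadir_exam` (argmin of the
#'       noise-free BMI over the exam schedule), `bw_out` flag and per-exam
#'       `miss_*` / `shrink_*` flags}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  ages <- config$exam_ages
  k <- length(ages)

  params <- with_seed(derive_seed(config$seed, "params"), {
    sample_growth_params(config, n)
  })

  age_mat <- matrix(rep(ages, each = n), nrow = n)
  if (config$jitter_ages && k == nrow(EXAM_WINDOWS)) {
    age_mat <- with_seed(derive_seed(config$seed, "ages"), {
      lo <- matrix(rep(EXAM_WINDOWS[, 1], each = n), nrow = n)
      hi <- matrix(rep(EXAM_WINDOWS[, 2], each = n), nrow = n)
      matrix(runif(n * k, lo, hi), nrow = n)
    })
  }

  bmi0 <- matrix(0, n, k)
  hgt0 <- matrix(0, n, k)
  for (j in seq_len(k)) {
    bmi0[, j] <- bmi_curve(age_mat[, j], params$b0, params$b_peak,
                           params$t_peak, params$b_nadir, params$t_nadir,
                           params$k_reb)
    hgt0[, j] <- height_curve(age_mat[, j], params$height_a, params$height_b,
                              params$height_c, params$height_d)
  }
  wgt0 <- bmi0 * (hgt0 / 100)^2
  true_nadir <- max.col(-bmi0, ties.method = "first")

  noisy <- with_seed(derive_seed(config$seed, "noise"), {
    list(
      h = hgt0 + matrix(rnorm(n * k, 0, config$noise_height_sd), n, k),
      w = wgt0 + matrix(rnorm(n * k, 0, config$noise_weight_sd), n, k)
    )
  })

  corr <- with_seed(derive_seed(config$seed, "corruption"), {
    # fixed-length draws so changing one probability leaves the rest of the
    # stream aligned
    list(
      miss = matrix(runif(n * k) < config$p_miss, n, k),
      shrink = matrix(runif(n * k) < config$p_shrink, n, k),
      shrink_amt = matrix(runif(n * k, 3, 10), n, k),
      bw_out = runif(n) < config$p_bw_out,
      bw_side = runif(n) < 0.5,
      bw_val = runif(n)
    )
  })

  h <- noisy$h - corr$shrink * corr$shrink_amt
  w <- noisy$w
  bw <- params$w0
  # out-of-range replacement: below 0.5 kg or above 5.0 kg
  bw_repl <- ifelse(corr$bw_side, 0.05 + 0.40 * corr$bw_val,
                    5.05 + 1.45 * corr$bw_val)
  bw[corr$bw_out] <- bw_repl[corr$bw_out]

  keep <- !corr$miss
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  exams <- data.frame(
    id = idx[, 1],
    exam_index = idx[, 2],
    age_months = age_mat[idx],
    # full precision: rounding would act as extra measurement noise and break
    # exact truth recovery on noise-free cohorts
    height_cm = h[idx],
    weight_kg = w[idx]
  )

  subjects <- data.frame(
    id = seq_len(n),
    sex = params$sex,
    birth_weight_kg = bw
  )

  truth <- cbind(
    data.frame(id = seq_len(n)),
    params,
    data.frame(true_nadir_exam = true_nadir, bw_out = as.integer(corr$bw_out))
  )
  miss_cols <- as.data.frame(corr$miss * 1L)
  names(miss_cols) <- paste0("miss_", seq_len(k))
  shrink_cols <- as.data.frame((corr$shrink & !corr$miss) * 1L)
  names(shrink_cols) <- paste0("shrink_", seq_len(k))
  truth <- cbind(truth, miss_cols, shrink_cols)

  structure(
    list(subjects = subjects, exams = exams, truth = truth, config = config),
    class = "synth_cohort"
  )
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic check-up cohort: %d subjects, %d exam records (seed %s)\n",
    nrow(x$subjects), nrow(x$exams), format(x$config$seed)
  ))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' @param cohort a `"synth_cohort"` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written
#'   (`subjects.csv`, `exams.csv`, `truth.csv`).
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    exams = file.path(dir, "exams.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write.csv(cohort$subjects, paths[["subjects"]], row.names = FALSE)
  write.csv(cohort$exams, paths[["exams"]], row.names = FALSE)
  write.csv(cohort$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
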