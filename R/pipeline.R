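#' Pipeline configuration
#'
#' Every knob of the end-to-end run in one validated object. Unknown
#' arguments are rejected, so typos in config files fail fast instead of
#' silently falling back to defaults.
#'
#' @param input_subjects,input_exams paths to input CSVs; leave `NULL` to
#'   simulate a cohort instead.
#' @param out_dir output directory for artifacts; `NULL` writes nothing.
#' @param sim a [sim_config()] used when simulating.
#' @param strict_increase QC strict-increase rule.
#' @param tie nadir tie-breaking rule (`"earliest"`/`"latest"`).
#' @param rwg_threshold rapid-weight-gain threshold, kg.
#' @param status_exam exam index for BMI weight status.
#' @param min_valid_exams subject-inclusion threshold.
#' @param seed seed for any simulation randomness.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_subjects = NULL, input_exams = NULL,
                            out_dir = NULL, sim = sim_config(),
                            strict_increase = TRUE,
                            tie = c("earliest", "latest"),
                            rwg_threshold = 5.1, status_exam = 6L,
                            min_valid_exams = 5L, seed = 1L) {
  tie <- match.arg(tie)
  stopifnot(inherits(sim, "sim_config"))
  if (!is.null(input_subjects) && is.null(input_exams)) {
    stop("input_exams required when input_subjects is given", call. = FALSE)
  }
  if (rwg_threshold <= 0) stop("rwg_threshold must be positive", call. = FALSE)
  if (min_valid_exams < 1L) stop("min_valid_exams must be >= 1", call. = FALSE)
  structure(list(
    input_subjects = input_subjects, input_exams = input_exams,
    out_dir = out_dir, sim = sim, strict_increase = isTRUE(strict_increase),
    tie = tie, rwg_threshold = rwg_threshold,
    status_exam = as.integer(status_exam),
    min_valid_exams = as.integer(min_valid_exams), seed = seed
  ), class = "pipeline_config")
}

#' Read a flat key: value configuration file
#'
#' Minimal YAML-like format: one `key: value` pair per line, `#` comments and
#' blank lines ignored. Keys are [pipeline_config()] arguments plus
#' `sim.<field>` entries forwarded to [sim_config()]. Unknown keys are
#' rejected before any computation.
#'
#' @param path file path.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad)) {
    stop("malformed config line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  if (anyDuplicated(keys)) stop("duplicate config keys", call. = FALSE)

  parse_val <- function(v) {
    if (v %in% c("true", "TRUE", "yes")) return(TRUE)
    if (v %in% c("false", "FALSE", "no")) return(FALSE)
    if (grepl("^\\[.*\\]$", v)) {
      return(as.numeric(strsplit(gsub("\\[|\\]", "", v), ",")[[1]]))
    }
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }

  sim_keys <- grepl("^sim\\.", keys)
  sim_args <- lapply(vals[sim_keys], parse_val)
  names(sim_args) <- sub("^sim\\.", "", keys[sim_keys])
  unknown <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown sim config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  top_args <- lapply(vals[!sim_keys], parse_val)
  names(top_args) <- keys[!sim_keys]
  unknown <- setdiff(names(top_args),
                     setdiff(names(formals(pipeline_config)), "sim"))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  top_args$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, top_args)
}

#' Read subject and exam CSV files
#'
#' The documented input schema (one row per exam, units kg/cm/months):
#' subjects need `id`, `sex`, `birth_weight_kg`; exams need `id`,
#' `exam_index`, `age_months`, `height_cm`, `weight_kg`. Malformed exam rows
#' (non-numeric or non-positive measurements, out-of-range exam index) are
#' routed to a reject file with their line numbers and the run continues;
#' they are never silently dropped.
#'
#' @param path CSV file path.
#' @param reject_path where to write rejected rows (default
#'   `<path>.rejects.csv`); `NA` disables writing (rejects still returned).
#' @return data frame; attribute `"rejects"` holds the rejected rows with a
#'   `line` and `reject_reason` column.
#' @export
read_exam_csv <- function(path, reject_path = NULL) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "exam_index", "age_months", "height_cm", "weight_kg")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("exam file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0L) {
    warning("exam file has headers only: empty cohort")
    attr(x, "rejects") <- x
    return(x)
  }
  for (col in c("exam_index", "age_months", "height_cm", "weight_kg")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  bad_num <- !is.finite(x$exam_index) | !is.finite(x$age_months) |
    !is.finite(x$height_cm) | !is.finite(x$weight_kg)
  bad_range <- !bad_num & (x$height_cm <= 0 | x$weight_kg <= 0 |
                             x$exam_index < 1 | x$exam_index != round(x$exam_index))
  bad <- bad_num | bad_range
  rejects <- x[bad, , drop = FALSE]
  if (nrow(rejects)) {
    rejects$line <- which(bad) + 1L  # header is line 1
    rejects$reject_reason <- ifelse(bad_num[bad], "non_numeric_field",
                                    "out_of_range_value")
    reject_path <- reject_path %||% paste0(path, ".rejects.csv")
    if (!is.na(reject_path)) {
      write.csv(rejects, reject_path, row.names = FALSE)
    }
    warning(sprintf("%d malformed exam row(s) rejected", nrow(rejects)))
  }
  out <- x[!bad, , drop = FALSE]
  out$exam_index <- as.integer(out$exam_index)
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' @rdname read_exam_csv
#' @export
read_subject_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "birth_weight_kg")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("subject file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x$birth_weight_kg <- suppressWarnings(as.numeric(x$birth_weight_kg))
  x
}

#' Write analysis artifacts as CSV files
#'
#' @param dir output directory (created if needed).
#' @param artifacts named list of data frames.
#' @return data frame manifest: `name`, `file`, `rows`, `md5`.
#' @export
write_tables <- function(dir, artifacts) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- integer(0); files <- character(0)
  for (nm in names(artifacts)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    write.csv(artifacts[[nm]], f, row.names = FALSE)
    files <- c(files, f); rows <- c(rows, nrow(artifacts[[nm]]))
  }
  data.frame(name = names(artifacts), file = files, rows = rows,
             md5 = unname(tools::md5sum(files)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> QC -> nadir detection and rebound
#' classification -> subgrouping -> analytic tables, optionally writing every
#' artifact to `out_dir`, and returns a run report whose stage counts chain
#' consistently. Identical configuration and seed give byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"run_report"`; the computed artifacts are in
#'   `$artifacts` and the stage accounting in `$counts`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)

  if (is.null(config$input_subjects)) {
    sim <- config$sim
    sim$seed <- config$seed
    cohort <- generate_cohort(validate_sim_config(unclass(sim)))
    subjects <- cohort$subjects
    exams <- cohort$exams
    truth <- cohort$truth
  } else {
    subjects <- read_subject_csv(config$input_subjects)
    exams <- read_exam_csv(config$input_exams)
    truth <- NULL
    nrej <- nrow(attr(exams, "rejects") %||% data.frame())
    if (nrej > 0) {
      warnings_log <- c(warnings_log,
                        sprintf("%d malformed exam rows rejected", nrej))
    }
  }

  qc <- apply_qc(subjects, exams, min_valid = config$min_valid_exams,
                 strict = config$strict_increase)
  clean <- qc_clean(qc)

  classification <- classify_cohort(clean, tie = config$tie)
  n_classified <- sum(!is.na(classification$nadir_exam))
  prev <- prevalence(classification, clean$subjects)
  cls_prev <- class_prevalence(classification$ar_class)

  subgroups <- subgroup_table(clean, rwg_threshold = config$rwg_threshold,
                              status_exam = config$status_exam)

  analysis <- merge(subgroups, classification, by = "id")
  # normal weight is the conventional reference for weight-status odds ratios
  analysis$bmi_status <- factor(analysis$bmi_status, ordered = FALSE)
  if ("normal" %in% levels(analysis$bmi_status)) {
    analysis$bmi_status <- stats::relevel(analysis$bmi_status, "normal")
  }
  analysis$ar_before_57 <- ar_before_57(analysis$ar_class)
  analysis$birth_weight_kg <-
    clean$subjects$birth_weight_kg[match(analysis$id, clean$subjects$id)]

  tab_status_ar <- crosstab(
    analysis[analysis$ar_class != "unclassified", ],
    "bmi_status", "ar_class"
  )
  status_tests <- tryCatch(
    list(chi = chi_square(drop_empty(tab_status_ar$counts)),
         lr = likelihood_ratio_test(drop_empty(tab_status_ar$counts))),
    error = function(e) {
      warnings_log <<- c(warnings_log, conditionMessage(e))
      NULL
    }
  )
  or_status <- tryCatch(
    fit_logistic(analysis, "ar_before_57", "bmi_status",
                 covariates = "birth_weight_kg"),
    error = function(e) {
      warnings_log <<- c(warnings_log,
                         paste("logistic fit failed:", conditionMessage(e)))
      NULL
    }
  )

  curves <- tryCatch(
    rbind(percentile_curves(clean, "male"), percentile_curves(clean, "female")),
    error = function(e) {
      warnings_log <<- c(warnings_log,
                         paste("percentile curves skipped:",
                               conditionMessage(e)))
      NULL
    }
  )
  sexcmp <- sex_compare(clean)

  artifacts <- list(
    qc_subjects = qc$subjects,
    classification = classification,
    prevalence = prev,
    class_prevalence = cls_prev,
    subgroups = subgroups,
    sex_comparison = sexcmp
  )
  if (!is.null(curves)) artifacts$percentile_curves <- as.data.frame(curves)
  if (!is.null(or_status)) artifacts$odds_ratios <- as.data.frame(or_status)

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    extra <- artifacts
    if (!is.null(truth)) extra$truth <- truth
    extra$subjects <- subjects
    extra$exams <- exams
    manifest <- write_tables(config$out_dir, extra)
  }

  report <- structure(list(
    package_version = as.character(packageVersion("bmirebound")),
    config = config,
    counts = c(
      input = nrow(subjects),
      excluded_birth_weight = qc$report$n_excluded_birth_weight,
      excluded_too_few_valid = qc$report$n_excluded_too_few_valid,
      included = qc$report$n_included,
      classified = n_classified,
      unclassified = qc$report$n_included - n_classified
    ),
    qc_report = qc$report,
    tests = status_tests,
    artifacts = artifacts,
    warnings = warnings_log,
    manifest = manifest
  ), class = "run_report")
  report
}

# drop all-zero rows/columns so tests on sparse simulated tables stay defined
drop_empty <- function(m) {
  m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (bmirebound ", x$package_version, ")\n", sep = "")
  cat("  stage counts:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("    %-24s %d\n", nm, x$counts[[nm]]))
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("    - ", w, "\n", sep = "")
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `synth` (write a simulated cohort), `qc`, `ar`, `stats`
#' (stage-wise runs) and `run` (full pipeline). Flags are `--key value`
#' pairs; `--config FILE` loads a flat key: value file first, with explicit
#' flags overriding it. Intended for use from the installed script
#' `inst/cli/bmirebound`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
bmirebound_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bmirebound <synth|qc|ar|stats|run> [--config FILE] [--n INT]",
    "[--seed INT] [--subjects FILE] [--exams FILE] [--out DIR]",
    "[--tie earliest|latest]"
  )
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest)) {
    if (!startsWith(rest[1], "--") || length(rest) < 2L) {
      message("bad argument: ", rest[1]); return(invisible(1L))
    }
    opts[[sub("^--", "", rest[1])]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
         else pipeline_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$n)) cfg$sim$n_subjects <- as.integer(opts$n)
  if (!is.null(opts$subjects)) cfg$input_subjects <- opts$subjects
  if (!is.null(opts$exams)) cfg$input_exams <- opts$exams
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  if (!is.null(opts$tie)) cfg$tie <- match.arg(opts$tie,
                                               c("earliest", "latest"))

  if (cmd == "synth") {
    sim <- cfg$sim; sim$seed <- cfg$seed
    cohort <- generate_cohort(validate_sim_config(unclass(sim)))
    if (is.null(cfg$out_dir)) { message("--out required"); return(invisible(1L)) }
    write_cohort_csv(cohort, cfg$out_dir)
    message(sprintf("wrote %d subjects to %s", nrow(cohort$subjects),
                    cfg$out_dir))
    return(invisible(0L))
  }
  if (cmd %in% c("qc", "ar", "stats", "run")) {
    rep <- run_pipeline(cfg)
    print(rep)
    return(invisible(0L))
  }
  message("unknown subcommand: ", cmd, "\n", usage)
  invisible(1L)
}
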