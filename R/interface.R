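# CSV ingestion, report writing, and the end-to-end study driver.
# The package ingests ROI-mean signal tables and cohort tables as CSV
# (comma-separated, header row, dot decimal); image-domain input is out of
# scope because the analysis is ROI-mean-based.

#' Read an ROI-mean signal table
#'
#' Expects columns `patient_id`, `b_value`, `signal` and optionally
#' `noise_sd`, one row per (patient, b-value). Validation errors report
#' the offending row.
#'
#' @param path CSV file path, or a data frame with the same columns.
#' @return The validated data frame.
#' @export
read_signals <- function(path) {
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("patient_id", "b_value", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("signal table is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad_b <- which(!is.finite(df$b_value) | df$b_value < 0)
  if (length(bad_b)) stop("negative or non-finite b_value at row(s): ",
                          paste(utils::head(bad_b), collapse = ", "),
                          call. = FALSE)
  bad_s <- which(!is.finite(df$signal) | df$signal <= 0)
  if (length(bad_s)) stop("non-positive signal at row(s): ",
                          paste(utils::head(bad_s), collapse = ", "),
                          call. = FALSE)
  dup <- duplicated(df[c("patient_id", "b_value")])
  if (any(dup)) stop("duplicated (patient_id, b_value) at row(s): ",
                     paste(utils::head(which(dup)), collapse = ", "),
                     call. = FALSE)
  df
}

#' @rdname read_signals
#' @param signals A validated signal table.
#' @param nsa Signal averages per b-value (default: the 12-b protocol
#'   tiers via [default_b_scheme()] when the b-values match, else 1).
#' @return `signals_to_curves()` returns a named list of
#'   [signal_curve()]s, one per patient.
#' @export
signals_to_curves <- function(signals, nsa = NULL) {
  signals <- read_signals(signals)
  def <- default_b_scheme()
  split_df <- split(signals, signals$patient_id)
  lapply(split_df, function(d) {
    d <- d[order(d$b_value), , drop = FALSE]
    this_nsa <- if (!is.null(nsa)) nsa
    else if (length(d$b_value) == length(def$b_values) &&
             all(d$b_value == def$b_values)) def$nsa
    else 1L
    sch <- b_scheme(d$b_value, this_nsa)
    ns <- if ("noise_sd" %in% names(d) && all(is.finite(d$noise_sd))) {
      d$noise_sd
    } else NULL
    signal_curve(sch, d$signal, ns)
  })
}

#' Read a cohort table
#'
#' Expects one row per patient with an `id` column; validates uniqueness
#' and, when present, positivity of lesion sizes (cm^2) and durations
#' (days). Either `duration_days` or both `scan1_date` and `scan2_date`
#' may supply the inter-scan interval (dates are converted to plain day
#' differences).
#'
#' @param path CSV file path, or a data frame.
#' @return The validated data frame (with `duration_days` filled in from
#'   dates when needed).
#' @export
read_cohort <- function(path) {
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!"id" %in% names(df)) stop("cohort table needs an 'id' column",
                                 call. = FALSE)
  if (anyDuplicated(df$id)) stop("duplicated patient id(s): ",
                                 paste(unique(df$id[duplicated(df$id)]),
                                       collapse = ", "), call. = FALSE)
  if (!"duration_days" %in% names(df) &&
      all(c("scan1_date", "scan2_date") %in% names(df))) {
    df$duration_days <- as.numeric(as.Date(df$scan2_date) -
                                     as.Date(df$scan1_date))
  }
  for (col in c("size_pre_cm2", "size_post_cm2", "duration_days")) {
    if (col %in% names(df)) {
      bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
      if (length(bad)) stop("non-positive ", col, " at row(s): ",
                            paste(utils::head(bad), collapse = ", "),
                            call. = FALSE)
    }
  }
  df
}

#' Run the full growth-rate study pipeline
#'
#' Executes the whole analysis on a signal table plus cohort table: fits
#' all five diffusion models per patient, computes directly measured
#' growth rates from the two-timepoint sizes, splits the cohort into
#' discovery and validation groups, runs the univariate screen, VIF
#' exclusion and multivariate regression on the discovery group, applies
#' the frozen equation to the validation group (r, ICC), runs k-fold
#' cross-validation on the whole cohort, and (when survival columns are
#' present) the ROC-cutoff + Kaplan-Meier/log-rank analyses for OS and
#' PFS. All thresholds and seeds are recorded in the report.
#'
#' @param signals Signal table (path or data frame; see [read_signals()]).
#' @param cohort Cohort table (path or data frame; see [read_cohort()]).
#' @param seed Integer seed for the cross-validation split.
#' @param validation_ids Patient ids forming the validation group; default
#'   is the last `ceiling(3 n / 11)` patients in table order (the
#'   acquisition-date convention: later scans validate).
#' @param vif_threshold VIF threshold (default 10).
#' @param alpha Significance level (default 0.05).
#' @param k Cross-validation folds (default 5).
#' @param config A [fit_config()].
#' @param predictors Candidate predictor columns for the univariate screen;
#'   default is every demographic/staging column present plus the 14
#'   fitted diffusion parameters.
#' @return A `study_report` list: `parameters` (per-patient 14-parameter
#'   table with convergence flags and per-b SNR), `cohort` (encoded, with
#'   growth rates), `screen`, `vif`, `regression`, `holdout`,
#'   `crossvalidation`, `survival` (or `NULL` with a warning when columns
#'   are absent), and `settings`.
#' @export
run_study <- function(signals, cohort, seed = 1L, validation_ids = NULL,
                      vif_threshold = 10, alpha = 0.05, k = 5L,
                      config = fit_config(), predictors = NULL) {
  curves <- signals_to_curves(signals)
  cohort <- read_cohort(cohort)
  if (!all(cohort$id %in% names(curves))) {
    stop("missing signal curves for patient(s): ",
         paste(utils::head(setdiff(cohort$id, names(curves))),
               collapse = ", "), call. = FALSE)
  }

  fits <- lapply(cohort$id, function(id) fit_all_models(curves[[id]],
                                                        config = config))
  par_tab <- as.data.frame(do.call(rbind, lapply(fits, parameter_vector)))
  par_tab$id <- cohort$id
  par_tab$converged <- vapply(fits, function(f) {
    all(vapply(f[c("mono", "biexp", "triexp", "sem", "dki")],
               `[[`, logical(1L), "converged"))
  }, logical(1L))
  snr_tab <- do.call(rbind, lapply(fits, `[[`, "snr"))
  colnames(snr_tab) <- paste0("snr_b", colnames(snr_tab))

  cohort <- merge(cohort[setdiff(names(cohort), names(par_tab)[1:14])],
                  par_tab, by = "id", sort = FALSE)
  cohort$growth_rate <- growth_rate(cohort$size_pre_cm2,
                                    cohort$size_post_cm2,
                                    cohort$duration_days)
  cohort <- encode_predictors(cohort)

  if (is.null(validation_ids)) {
    n_val <- ceiling(nrow(cohort) * 3 / 11)  # 55 patients -> 15
    validation_ids <- utils::tail(cohort$id, n_val)
  }
  disc <- cohort[!cohort$id %in% validation_ids, , drop = FALSE]
  val <- cohort[cohort$id %in% validation_ids, , drop = FALSE]

  if (is.null(predictors)) {
    predictors <- intersect(
      c("age", "sex", "site", "t_stage", "n_stage", "smoking", "alcohol",
        "size_pre_cm2", "adc", "f", "d_star", "d", "f1", "f2", "f3",
        "d1", "d2", "d3", "alpha", "ddc", "d_k", "k"),
      names(cohort))
  }

  screen <- univariate_screen(disc, predictors, alpha = alpha)
  sig <- screen$predictor[screen$significant]
  if (length(sig) == 0L) {
    stop("no predictor survives the univariate screen", call. = FALSE)
  }
  vif <- if (length(sig) >= 2L) {
    vif_screen(disc, sig, vif_threshold)
  } else list(retained = sig,
              removed = data.frame(predictor = character(), vif = numeric()),
              vif = stats::setNames(1, sig))
  reg <- multivariate_regress(disc, vif$retained, alpha = alpha)
  holdout <- holdout_validate(reg, val)
  cv <- crossvalidate(cohort, predictors, k = k, seed = seed,
                      vif_threshold = vif_threshold, alpha = alpha)

  surv <- NULL
  if (all(c("os_months", "os_event") %in% names(cohort))) {
    cohort$estimated_growth_rate <-
      as.numeric(stats::predict(reg$model, newdata = cohort))
    surv <- list()
    for (oc in c("os", "pfs")) {
      if (!all(paste0(oc, c("_months", "_event")) %in% names(cohort))) next
      surv[[oc]] <- list(
        measured = survival_by_growth(cohort, "growth_rate", oc),
        estimated = survival_by_growth(cohort, "estimated_growth_rate", oc))
    }
  } else {
    warning("survival columns absent; survival analysis skipped",
            call. = FALSE)
  }

  structure(list(parameters = cbind(par_tab, snr_tab),
                 cohort = cohort,
                 screen = screen,
                 vif = vif,
                 regression = reg,
                 holdout = holdout,
                 crossvalidation = cv,
                 survival = surv,
                 settings = list(seed = seed, vif_threshold = vif_threshold,
                                 alpha = alpha, k = k,
                                 validation_ids = validation_ids,
                                 version = as.character(
                                   utils::packageVersion("dwigrowth")))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Growth-rate study report (dwigrowth",
      x$settings$version, ")\n")
  cat(sprintf("  patients: %d (discovery %d / validation %d)\n",
              nrow(x$cohort),
              nrow(x$cohort) - length(x$settings$validation_ids),
              length(x$settings$validation_ids)))
  cat("  significant in univariate screen:",
      paste(x$screen$predictor[x$screen$significant], collapse = ", "), "\n")
  cat("  retained after VIF:", paste(x$vif$retained, collapse = ", "), "\n")
  print(x$regression)
  cat(sprintf("  holdout: r = %.3f (%s), ICC = %.3f\n", x$holdout$r,
              classify_correlation(x$holdout$r), x$holdout$icc))
  cat(sprintf("  %d-fold CV: mean r = %.3f, mean ICC = %.3f\n",
              x$settings$k, x$crossvalidation$mean_r,
              x$crossvalidation$mean_icc))
  if (!is.null(x$survival)) {
    for (oc in names(x$survival)) {
      s <- x$survival[[oc]]
      cat(sprintf(
        "  %s: cutoff %.1f (measured) / %.1f (estimated); log-rank p %.3g / %.3g\n",
        toupper(oc), s$measured$cutoff$cutoff, s$estimated$cutoff$cutoff,
        s$measured$logrank$p, s$estimated$logrank$p))
    }
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes machine-readable outputs: the per-patient parameter table and
#' screen results as CSV, and a JSON summary (equation, validation
#' metrics, fold metrics, survival cutoffs and p-values, settings and
#' seeds).
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    parameters = file.path(dir, "parameters.csv"),
    screen = file.path(dir, "univariate_screen.csv"),
    folds = file.path(dir, "cv_folds.csv"),
    summary = file.path(dir, "summary.json"))
  utils::write.csv(report$parameters, paths[["parameters"]],
                   row.names = FALSE)
  utils::write.csv(report$screen, paths[["screen"]], row.names = FALSE)
  utils::write.csv(report$crossvalidation$folds, paths[["folds"]],
                   row.names = FALSE)
  summary <- list(
    equation = list(predictors = report$regression$predictors,
                    coefficients = as.list(report$regression$coefficients),
                    intercept = report$regression$intercept,
                    std_coef = as.list(report$regression$std_coef),
                    multiple_r = report$regression$multiple_r),
    holdout = list(r = report$holdout$r, icc = report$holdout$icc,
                   n = report$holdout$n),
    crossvalidation = list(mean_r = report$crossvalidation$mean_r,
                           mean_icc = report$crossvalidation$mean_icc),
    survival = if (is.null(report$survival)) NULL else {
      lapply(report$survival, function(s) list(
        cutoff_measured = s$measured$cutoff$cutoff,
        cutoff_estimated = s$estimated$cutoff$cutoff,
        logrank_p_measured = s$measured$logrank$p,
        logrank_p_estimated = s$estimated$logrank$p))
    },
    settings = report$settings)
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' @rdname read_signals
#' @param curves Named list of [signal_curve()]s.
#' @return `curves_to_signals()` returns the long-format signal table
#'   (inverse of [signals_to_curves()]).
#' @export
curves_to_signals <- function(curves) {
  do.call(rbind, lapply(names(curves), function(id) {
    cv <- curves[[id]]
    d <- data.frame(patient_id = id, b_value = cv$scheme$b_values,
                    signal = cv$signal)
    if (!is.null(cv$noise_sd)) d$noise_sd <- cv$noise_sd
    d
  }))
}
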