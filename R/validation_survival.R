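# Holdout validation, k-fold cross-validation, ROC closest-corner cutoffs,
# Kaplan-Meier estimation and log-rank comparison of growth-rate groups.

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Holdout validation of a growth equation
#'
#' Applies a frozen prediction equation (or fitted regression) to an
#' independent validation cohort and reports the Pearson correlation and
#' ICC(2,1) between predicted and directly measured growth rates.
#'
#' @param eq A [growth_equation()] or `growth_regression`.
#' @param validation Cohort data frame carrying the equation's predictor
#'   columns (for the packaged equation: `d2`, `d3`) and the measured
#'   outcome.
#' @param outcome Measured outcome column (default `"growth_rate"`).
#' @return List with `r`, `icc`, `predicted`, `measured` and `n`. When the
#'   predictions are constant `r` is `NA`.
#' @export
holdout_validate <- function(eq, validation, outcome = "growth_rate") {
  stopifnot(is.data.frame(validation), outcome %in% names(validation))
  if (nrow(validation) < 3L) {
    stop("holdout validation needs n >= 3", call. = FALSE)
  }
  pred <- if (inherits(eq, "growth_equation")) {
    stopifnot(all(c("d2", "d3") %in% names(validation)))
    predict_growth(eq, validation$d2, validation$d3)
  } else if (inherits(eq, "growth_regression")) {
    as.numeric(stats::predict(eq$model, newdata = validation))
  } else {
    stop("eq must be a growth_equation or growth_regression", call. = FALSE)
  }
  meas <- validation[[outcome]]
  r <- if (stats::sd(pred) == 0 || stats::sd(meas) == 0) NA_real_ else {
    stats::cor(pred, meas)
  }
  list(r = r, icc = icc(cbind(predicted = pred, measured = meas))$icc,
       predicted = pred, measured = meas, n = length(meas))
}

#' Seeded k-fold partition
#'
#' Randomly partitions ids into k folds with sizes as equal as possible
#' (n = 55, k = 5 gives five test folds of 11 and training sets of 44).
#' The same seed always yields the same assignment.
#'
#' @param ids Vector of patient identifiers (must be unique).
#' @param k Number of folds (default 5); must not exceed `length(ids)`.
#' @param seed Integer seed (mandatory: every stochastic split in this
#'   package takes an explicit seed).
#' @return A `fold_assignment`: list with `fold` (named integer vector)
#'   and `folds` (list of k test-id vectors).
#' @export
kfold_split <- function(ids, k = 5L, seed) {
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  n <- length(ids)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("need 2 <= k <= n", call. = FALSE)
  labels <- rep(seq_len(k), length.out = n)  # sizes differ by at most 1
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- labels
  names(fold) <- as.character(ids)
  structure(list(fold = fold,
                 folds = split(ids, fold)),
            class = "fold_assignment")
}

#' Five-fold cross-validation of the growth-rate pipeline
#'
#' Repeats the discovery-group analysis (univariate screen, VIF exclusion,
#' multivariate regression) on each training set and the validation-group
#' analysis (predicted-vs-measured r and ICC) on the matching test fold.
#' A fold in which no predictor survives the screen is recorded as `NA`
#' metrics and the run continues.
#'
#' @param table Encoded cohort data frame with an `id` column, predictor
#'   columns and the outcome.
#' @param predictors Candidate predictor columns for the screen.
#' @param outcome Outcome column (default `"growth_rate"`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold split.
#' @param vif_threshold VIF threshold (default 10).
#' @param alpha Significance level (default 0.05).
#' @return List with `folds` (data frame: fold, n_train, n_test, r, icc,
#'   n_predictors), `mean_r`, `mean_icc`, and `assignment`.
#' @export
crossvalidate <- function(table, predictors, outcome = "growth_rate",
                          k = 5L, seed, vif_threshold = 10, alpha = 0.05) {
  stopifnot(is.data.frame(table), "id" %in% names(table))
  assignment <- kfold_split(table$id, k = k, seed = seed)
  per_fold <- lapply(seq_len(k), function(i) {
    test_ids <- assignment$folds[[i]]
    train <- table[!table$id %in% test_ids, , drop = FALSE]
    test <- table[table$id %in% test_ids, , drop = FALSE]
    row <- data.frame(fold = i, n_train = nrow(train), n_test = nrow(test),
                      r = NA_real_, icc = NA_real_, n_predictors = 0L)
    scr <- univariate_screen(train, predictors, outcome, alpha)
    sig <- scr$predictor[scr$significant]
    if (length(sig) == 0L) return(row)
    kept <- if (length(sig) >= 2L) {
      vif_screen(train, sig, vif_threshold, outcome)$retained
    } else sig
    reg <- multivariate_regress(train, kept, outcome, alpha)
    val <- tryCatch(holdout_validate(reg, test, outcome),
                    error = function(e) NULL)
    if (!is.null(val)) {
      row$r <- val$r
      row$icc <- val$icc
    }
    row$n_predictors <- length(reg$predictors)
    row
  })
  folds <- do.call(rbind, per_fold)
  list(folds = folds,
       mean_r = mean(folds$r, na.rm = TRUE),
       mean_icc = mean(folds$icc, na.rm = TRUE),
       assignment = assignment)
}

#' ROC closest-to-corner cutoff
#'
#' Evaluates the empirical ROC curve over candidate thresholds (the
#' midpoints between adjacent sorted unique scores; higher score =
#' positive class) and returns the threshold minimizing the Euclidean
#' distance to the upper-left corner,
#' \eqn{\sqrt{(1-sens)^2 + (1-spec)^2}}. When several thresholds tie, the
#' one with the higher sensitivity wins.
#'
#' @param scores Numeric predictor values (e.g. growth rates).
#' @param labels Binary outcome (logical or 0/1); both classes must be
#'   present.
#' @return A `cutoff_result`: `cutoff`, `sensitivity`, `specificity`,
#'   `distance` and `roc` (data frame of all candidate thresholds).
#' @examples
#' roc_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))  # cutoff 2.5
#' @export
roc_cutoff <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing values", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  su <- sort(unique(scores))
  if (length(su) < 2L) stop("scores are constant", call. = FALSE)
  thr <- (su[-1L] + su[-length(su)]) / 2
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1L))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1L))
  dist <- sqrt((1 - sens)^2 + (1 - spec)^2)
  best <- which(dist <= min(dist) + 1e-12)
  if (length(best) > 1L) best <- best[which.max(sens[best])]
  structure(list(cutoff = thr[best], sensitivity = sens[best],
                 specificity = spec[best], distance = dist[best],
                 roc = data.frame(threshold = thr, sensitivity = sens,
                                  specificity = spec, distance = dist)),
            class = "cutoff_result")
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate with right censoring, returned as a step table.
#' Survival is 1 before the first event.
#'
#' @param time Follow-up times (months), > 0.
#' @param event Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return A `km_curve`: data frame `table` with columns `time`, `n_risk`,
#'   `n_event`, `survival`, plus the underlying `survival::survfit` object
#'   in `fit`.
#' @export
kaplan_meier <- function(time, event) {
  time <- as.numeric(time); event <- as.integer(as.logical(event))
  if (length(time) < 1L) stop("need at least one record", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("follow-up times must be > 0", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  structure(list(table = data.frame(time = fit$time, n_risk = fit$n.risk,
                                    n_event = fit$n.event,
                                    survival = fit$surv),
                 fit = fit),
            class = "km_curve")
}

#' @rdname kaplan_meier
#' @param km A `km_curve`.
#' @param t Times at which to evaluate the step function.
#' @return `km_survival()` returns S(t) at the requested times.
#' @export
km_survival <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  tab <- km$table[km$table$n_event > 0, , drop = FALSE]
  vapply(t, function(ti) {
    below <- tab$time <= ti
    if (!any(below)) 1 else tab$survival[max(which(below))]
  }, numeric(1L))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df, hypergeometric variance, no
#' continuity correction) comparing the survival of two groups, with a
#' two-sided p-value.
#'
#' @param time Follow-up times, > 0.
#' @param event Event indicators.
#' @param group Two-level group labels.
#' @return List with `chi2`, `p` and `df`. With no events at all the test
#'   is undefined and `NA` is returned with a warning.
#' @export
logrank <- function(time, event, group) {
  time <- as.numeric(time); event <- as.integer(as.logical(event))
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("need exactly two groups", call. = FALSE)
  if (any(table(group) == 0L)) stop("both groups must be non-empty",
                                    call. = FALSE)
  if (sum(event) == 0L) {
    warning("no events in either group; log-rank undefined", call. = FALSE)
    return(list(chi2 = NA_real_, p = NA_real_, df = 1L))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi2 = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       df = 1L)
}

#' Survival analysis by growth-rate group
#'
#' Dichotomizes patients at the ROC closest-corner cutoff of the chosen
#' growth-rate column against the end-of-follow-up outcome status
#' (non-survivor for OS, progression for PFS), then compares the
#' Kaplan-Meier curves of the low and high growth-rate groups with the
#' log-rank test.
#'
#' @param table Cohort data frame.
#' @param rate_column Growth-rate column to dichotomize (measured or
#'   estimated).
#' @param outcome `"os"` or `"pfs"`; uses columns `os_months`/`os_event`
#'   or `pfs_months`/`pfs_event`.
#' @return List with `cutoff` (a `cutoff_result`), `km_low`, `km_high`,
#'   `logrank` and `group` (the per-patient high-rate flag).
#' @export
survival_by_growth <- function(table, rate_column = "growth_rate",
                               outcome = c("os", "pfs")) {
  outcome <- match.arg(outcome)
  tcol <- paste0(outcome, "_months"); ecol <- paste0(outcome, "_event")
  stopifnot(is.data.frame(table),
            all(c(rate_column, tcol, ecol) %in% names(table)))
  rate <- table[[rate_column]]
  time <- table[[tcol]]; event <- as.integer(as.logical(table[[ecol]]))
  if (length(unique(event)) < 2L) {
    warning("outcome status is single-class (e.g. all censored); ",
            "cutoff and log-rank undefined", call. = FALSE)
    return(list(cutoff = NULL, km_low = NULL, km_high = NULL,
                km_all = kaplan_meier(time, event),
                logrank = list(chi2 = NA_real_, p = NA_real_, df = 1L),
                group = rep(NA, length(rate))))
  }
  cut <- roc_cutoff(rate, event)
  high <- rate >= cut$cutoff
  lr <- if (sum(event) == 0L) {
    warning("all records censored; log-rank undefined", call. = FALSE)
    list(chi2 = NA_real_, p = NA_real_, df = 1L)
  } else {
    logrank(time, event, factor(high, levels = c(FALSE, TRUE),
                                labels = c("low", "high")))
  }
  list(cutoff = cut,
       km_low = kaplan_meier(time[!high], event[!high]),
       km_high = kaplan_meier(time[high], event[high]),
       logrank = lr,
       group = high)
}
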