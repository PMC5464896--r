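# Univariate screening, VIF multicollinearity exclusion, multivariate
# regression with standardized coefficients, ICC, Mann-Whitney, and
# correlation-strength classification.

#' Encode cohort predictors as numeric design columns
#'
#' Converts the categorical patient characteristics to the numeric codes
#' used by the regression screen: binary codes for sex (male = 0,
#' female = 1), primary-site group (nasal cavity/paranasal sinus = 0,
#' pharynx/oral cavity = 1) and smoking status (non-smoker = 0,
#' smoker = 1); ordinal codes for T-stage (1-4; T4a and T4b both code 4),
#' N-stage (0-3) and alcohol use (occasional-or-non-drinker = 0,
#' moderate = 1, heavy = 2). Numeric columns pass through unchanged.
#' Unknown category labels raise an error naming the offending value.
#'
#' @param table A cohort data frame; recognized categorical columns are
#'   `sex`, `site`, `smoking`, `alcohol`, `t_stage`, `n_stage`.
#' @return The data frame with the recognized columns replaced by numeric
#'   codes. Zero-variance columns are flagged in the
#'   `attr(, "zero_variance")` attribute.
#' @export
encode_predictors <- function(table) {
  stopifnot(is.data.frame(table))
  enc <- table

  code_map <- function(x, map, what) {
    if (is.numeric(x)) return(x)
    key <- tolower(trimws(as.character(x)))
    out <- map[key]
    if (anyNA(out)) {
      bad <- unique(key[is.na(out)])
      stop("unknown ", what, " value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    unname(out)
  }

  if ("sex" %in% names(enc)) {
    enc$sex <- code_map(enc$sex,
                        c(male = 0, m = 0, female = 1, f = 1), "sex")
  }
  if ("site" %in% names(enc)) {
    enc$site <- code_map(enc$site, c(
      "nasal cavity" = 0, "paranasal sinus" = 0, "nasal_paranasal" = 0,
      "oral cavity" = 1, "oropharynx" = 1, "hypopharynx" = 1,
      "pharynx" = 1, "pharynx_oral" = 1), "primary site")
  }
  if ("smoking" %in% names(enc)) {
    if (is.logical(enc$smoking)) {
      enc$smoking <- as.numeric(enc$smoking)
    } else {
      enc$smoking <- code_map(enc$smoking, c(
        "non-smoker" = 0, "nonsmoker" = 0, "never" = 0,
        "smoker" = 1, "tobacco smoker" = 1), "smoking status")
    }
  }
  if ("alcohol" %in% names(enc)) {
    enc$alcohol <- code_map(enc$alcohol, c(
      "none" = 0, "non-drinker" = 0, "occasional" = 0,
      "occasional or non-drinker" = 0,
      "moderate" = 1, "moderate use" = 1,
      "heavy" = 2, "heavy use" = 2), "alcohol use")
  }
  if ("t_stage" %in% names(enc)) {
    enc$t_stage <- code_map(enc$t_stage, c(
      "t1" = 1, "t2" = 2, "t3" = 3, "t4" = 4, "t4a" = 4, "t4b" = 4,
      "1" = 1, "2" = 2, "3" = 3, "4" = 4), "T-stage")
  }
  if ("n_stage" %in% names(enc)) {
    enc$n_stage <- code_map(enc$n_stage, c(
      "n0" = 0, "n1" = 1, "n2" = 2, "n3" = 3,
      "0" = 0, "1" = 1, "2" = 2, "3" = 3), "N-stage")
  }

  num <- vapply(enc, is.numeric, logical(1L))
  zv <- names(enc)[num][vapply(enc[num], function(x) {
    stats::var(x) == 0
  }, logical(1L))]
  attr(enc, "zero_variance") <- zv
  enc
}

#' Univariate regression screen
#'
#' Simple linear regression of the outcome on each candidate predictor in
#' turn, reporting the signed Pearson correlation coefficient and the
#' slope-t p-value (identical to the correlation-test p-value), with a
#' significance flag at `alpha`.
#'
#' @param table Encoded cohort data frame (see [encode_predictors()]).
#' @param predictors Character vector of predictor column names; default is
#'   every numeric column other than the outcome.
#' @param outcome Outcome column name (default `"growth_rate"`).
#' @param alpha Significance level for the flag (default 0.05).
#' @return Data frame with columns `predictor`, `r`, `p`, `significant`.
#'   Zero-variance predictors get `NA` for `r` and `p`.
#' @export
univariate_screen <- function(table, predictors = NULL,
                              outcome = "growth_rate", alpha = 0.05) {
  stopifnot(is.data.frame(table), outcome %in% names(table))
  y <- table[[outcome]]
  if (is.null(predictors)) {
    num <- names(table)[vapply(table, is.numeric, logical(1L))]
    predictors <- setdiff(num, c(outcome, "id", "patient_id"))
  }
  n <- length(y)
  if (n < 4L) stop("need at least 4 patients for the screen", call. = FALSE)
  res <- lapply(predictors, function(nm) {
    x <- table[[nm]]
    if (!is.numeric(x)) {
      stop("predictor '", nm, "' is not numeric; encode it first",
           call. = FALSE)
    }
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      return(data.frame(predictor = nm, r = NA_real_, p = NA_real_,
                        significant = FALSE))
    }
    r <- stats::cor(x, y)
    tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    data.frame(predictor = nm, r = r, p = p,
               significant = is.finite(p) && p < alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Variance-inflation-factor multicollinearity screen
#'
#' Computes VIF_j = 1 / (1 - R^2_j) for each candidate (R^2_j from
#' regressing candidate j on the remaining candidates) and iteratively
#' removes the candidate with the largest VIF above the threshold until
#' all remaining VIFs are at or below it. Ties (including multiple
#' infinite VIFs from perfect collinearity) are broken by removing the
#' candidate with the weaker univariate correlation with the outcome.
#' The procedure is idempotent: re-screening the retained set removes
#' nothing.
#'
#' @param table Encoded cohort data frame.
#' @param candidates Character vector of >= 2 candidate predictor columns.
#' @param threshold VIF threshold (default 10).
#' @param outcome Outcome column used only for tie-breaking (default
#'   `"growth_rate"`).
#' @return List with `retained` (names), `removed` (data frame of name and
#'   VIF at removal) and `vif` (named VIFs of the retained set).
#' @export
vif_screen <- function(table, candidates, threshold = 10,
                       outcome = "growth_rate") {
  stopifnot(is.data.frame(table), length(candidates) >= 2L,
            all(candidates %in% names(table)))
  x <- as.matrix(table[candidates])
  storage.mode(x) <- "double"
  y <- if (outcome %in% names(table)) table[[outcome]] else NULL

  vif_of <- function(cols) {
    vapply(seq_along(cols), function(j) {
      xj <- x[, cols[j]]
      others <- x[, cols[-j], drop = FALSE]
      fit <- stats::lm.fit(cbind(1, others), xj)
      rss <- sum(fit$residuals^2)
      tss <- sum((xj - mean(xj))^2)
      if (tss == 0) return(Inf)
      r2 <- 1 - rss / tss
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1L))
  }

  keep <- candidates
  removed <- data.frame(predictor = character(), vif = numeric())
  while (length(keep) >= 2L) {
    v <- vif_of(keep)
    over <- which(v > threshold)
    if (length(over) == 0L) break
    worst <- over[v[over] == max(v[over])]
    if (length(worst) > 1L && !is.null(y)) {
      # weaker outcome correlation goes first
      rr <- abs(vapply(keep[worst], function(nm) {
        if (stats::var(x[, nm]) == 0) 0 else stats::cor(x[, nm], y)
      }, numeric(1L)))
      worst <- worst[which.min(rr)]
    } else {
      worst <- worst[1L]
    }
    removed <- rbind(removed,
                     data.frame(predictor = keep[worst], vif = v[worst]))
    keep <- keep[-worst]
  }
  final_vif <- if (length(keep) >= 2L) {
    stats::setNames(vif_of(keep), keep)
  } else {
    stats::setNames(rep(1, length(keep)), keep)
  }
  list(retained = keep, removed = removed, vif = final_vif)
}

#' Multivariate growth-rate regression
#'
#' Ordinary least squares of the outcome on the post-VIF predictor set,
#' followed by backward elimination of predictors whose coefficient
#' p-value is at or above `alpha`, so that the final equation keeps only
#' significant terms. Reports raw coefficients, standardized partial
#' regression coefficients (raw coefficient times SD(x)/SD(y)), per-term
#' p-values, and the multiple correlation coefficient r between fitted and
#' observed outcome.
#'
#' @param table Encoded cohort data frame.
#' @param predictors Character vector of predictor columns (post
#'   [vif_screen()]).
#' @param outcome Outcome column name (default `"growth_rate"`).
#' @param alpha Retention threshold for coefficient p-values (default
#'   0.05). Set to 1 to keep all predictors.
#' @return A `growth_regression` object: `predictors`, `coefficients`
#'   (named, without intercept), `intercept`, `std_coef`, `p_values`,
#'   `multiple_r`, `fitted`, `model` (the underlying `lm`), and `dropped`.
#' @export
multivariate_regress <- function(table, predictors,
                                 outcome = "growth_rate", alpha = 0.05) {
  stopifnot(is.data.frame(table), length(predictors) >= 1L,
            all(predictors %in% names(table)), outcome %in% names(table))
  n <- nrow(table)
  if (n < length(predictors) + 3L) {
    stop("need n >= number of coefficients + 2 for the regression",
         call. = FALSE)
  }
  dropped <- character()
  keep <- predictors
  repeat {
    fml <- stats::reformulate(keep, response = outcome)
    fit <- stats::lm(fml, data = table)
    if (any(is.na(stats::coef(fit)))) {
      stop("design is rank deficient; run vif_screen first", call. = FALSE)
    }
    pv <- summary(fit)$coefficients[-1L, 4L]
    worst <- which.max(pv)
    if (length(keep) > 1L && pv[worst] >= alpha) {
      dropped <- c(dropped, keep[worst])
      keep <- keep[-worst]
    } else break
  }
  co <- stats::coef(fit)
  y <- table[[outcome]]
  sx <- vapply(keep, function(nm) stats::sd(table[[nm]]), numeric(1L))
  std <- co[keep] * sx / stats::sd(y)
  fitted <- stats::fitted(fit)
  mr <- if (stats::sd(fitted) == 0) NA_real_ else abs(stats::cor(fitted, y))
  structure(list(predictors = keep,
                 coefficients = co[keep],
                 intercept = co[[1L]],
                 std_coef = std,
                 p_values = summary(fit)$coefficients[-1L, 4L],
                 multiple_r = mr,
                 fitted = fitted,
                 model = fit,
                 dropped = dropped),
            class = "growth_regression")
}

#' @export
print.growth_regression <- function(x, ...) {
  cat("Growth-rate regression:", deparse(stats::formula(x$model)), "\n")
  tab <- data.frame(coef = x$coefficients, std_coef = x$std_coef,
                    p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("intercept: %.4g   multiple r: %.3f (%s)\n",
              x$intercept, x$multiple_r, classify_correlation(x$multiple_r)))
  if (length(x$dropped)) {
    cat("dropped (p >= threshold):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname multivariate_regress
#' @param reg A `growth_regression` whose predictors are exactly `d2` and
#'   `d3`.
#' @return `as_growth_equation()` converts such a fit to a
#'   [growth_equation()].
#' @export
as_growth_equation <- function(reg) {
  stopifnot(inherits(reg, "growth_regression"))
  if (!setequal(reg$predictors, c("d2", "d3"))) {
    stop("regression does not have predictors {d2, d3}", call. = FALSE)
  }
  growth_equation(coef_d2 = reg$coefficients[["d2"]],
                  coef_d3 = reg$coefficients[["d3"]],
                  intercept = reg$intercept)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures, from the
#' ANOVA mean squares of the n subjects x k raters matrix:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the row (subject), column
#' (rater) and residual mean squares.
#'
#' @param ratings Numeric matrix or data frame, one row per subject, one
#'   column per rater; complete, n >= 2 subjects and k >= 2 raters.
#' @return An `icc_result` list: `icc`, `ms` (mean squares), `components`
#'   (subject / rater / residual variance components). When every cell is
#'   identical the ICC is undefined and returned as `NA`.
#' @examples
#' icc(cbind(r1 = c(1, 2, 3, 4), r2 = c(2, 3, 4, 5)))
#' @export
icc <- function(ratings) {
  x <- as.matrix(ratings)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("ratings must be complete", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters",
                             call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  val <- if (ss_tot == 0) NA_real_ else (msr - mse) / denom
  structure(list(icc = val,
                 ms = c(subjects = msr, raters = msc, residual = mse),
                 components = c(subject = (msr - mse) / k,
                                rater = (msc - mse) / n,
                                residual = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) absolute agreement, single measures: %.4f\n", x$icc))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. When both
#' groups have at most 8 observations the null distribution of U is
#' enumerated exactly over all group assignments (midranks, so ties are
#' handled); otherwise the normal approximation with tie-corrected
#' variance is used. The reported U is that of the first sample.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param exact_max Largest per-group size for which full enumeration is
#'   used (default 8).
#' @return List with `u` (first sample's U), `p` (two-sided) and `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
    p <- min(p, 1)
    method <- "exact enumeration"
  } else {
    nn <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    v <- n1 * n2 / 12 * (nn + 1 - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  list(u = u_obs, p = p, method = method)
}

#' Correlation-strength classification
#'
#' Classifies the magnitude of a correlation or agreement coefficient into
#' the conventional descriptive bands: poor (< 0.2), fair (0.2 to < 0.41),
#' moderate (0.41 to < 0.61), good (0.61 to < 0.81) and excellent
#' (>= 0.81).
#'
#' @param r Correlation coefficient(s); must satisfy |r| <= 1.
#' @return Character vector of band labels.
#' @examples
#' classify_correlation(c(0.74, 0.66, 0))
#' @export
classify_correlation <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop("correlation coefficients must be finite with |r| <= 1",
         call. = FALSE)
  }
  as.character(cut(abs(r), breaks = c(-Inf, 0.2, 0.41, 0.61, 0.81, Inf),
                   labels = c("poor", "fair", "moderate", "good", "excellent"),
                   right = FALSE))
}
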