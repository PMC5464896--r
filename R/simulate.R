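# Synthetic signal curves, cohorts and survival outcomes with the
# statistical structure the analysis pipeline assumes, so every stage is
# testable without patient data.

# Truncated-normal draws by resampling (bounds are physical, so the
# acceptance region has high probability and resampling terminates fast).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Simulate an ROI-mean signal curve
#'
#' Evaluates the chosen forward diffusion model at every b-value of the
#' scheme and adds measurement noise. The noise SD at b = 0 is
#' sigma = S0 / SNR; each b-value's SD is scaled by the square root of its
#' number of signal averages (sigma / sqrt(NSA)). Rician noise (the
#' magnitude-MR default) takes the modulus of the complex signal
#' (S + N(0, sigma_b), N(0, sigma_b)); Gaussian noise adds N(0, sigma_b)
#' directly.
#'
#' @param model One of `"mono"`, `"biexp"`, `"triexp"`, `"sem"`, `"dki"`.
#' @param params Parameter record for the model (see [diffusion_params]).
#' @param scheme A [b_scheme()] (default [default_b_scheme()]).
#' @param s0 Signal at b = 0 (default 1000, arbitrary units).
#' @param snr Signal-to-noise ratio at b = 0 (ignored for `noise =
#'   "none"`).
#' @param noise `"rician"`, `"gaussian"` or `"none"`.
#' @param seed Integer seed (required unless `noise = "none"`).
#' @return A [signal_curve()] with `noise_sd` recording the per-b SD.
#' @export
simulate_signal <- function(model, params, scheme = default_b_scheme(),
                            s0 = 1000, snr = 100,
                            noise = c("rician", "gaussian", "none"),
                            seed = NULL) {
  noise <- match.arg(noise)
  clean <- model_signal(model, scheme$b_values, s0, params)
  if (noise == "none") {
    return(signal_curve(scheme, clean))
  }
  if (is.null(seed)) stop("a seed is required for noisy simulation",
                          call. = FALSE)
  if (!is.finite(snr) || snr <= 0) stop("snr must be > 0", call. = FALSE)
  sigma <- s0 / snr
  sd_b <- sigma / sqrt(scheme$nsa)
  noisy <- with_seed(seed, {
    if (noise == "rician") {
      re <- clean + stats::rnorm(length(clean), 0, sd_b)
      im <- stats::rnorm(length(clean), 0, sd_b)
      sqrt(re^2 + im^2)
    } else {
      pmax(clean + stats::rnorm(length(clean), 0, sd_b), 1e-9)
    }
  })
  signal_curve(scheme, noisy, noise_sd = sd_b)
}

# Default cross-correlation matrix of the 6 jointly-drawn diffusion
# coefficients: the intermediate-diffusion block {adc, d, ddc, d_k, d2} is
# strongly mutually correlated (they index nearly the same tissue
# property), d3 moderately correlated with each.
diffusion_cor_matrix <- function(block_r = 0.9, d3_r = 0.45) {
  nm <- c("adc", "d", "ddc", "d_k", "d2", "d3")
  m <- diag(6)
  dimnames(m) <- list(nm, nm)
  block <- nm[1:5]
  m[block, block] <- block_r
  diag(m) <- 1
  m["d3", block] <- d3_r
  m[block, "d3"] <- d3_r
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    stop("infeasible correlation structure (block_r = ", block_r,
         ", d3_r = ", d3_r, "): not positive definite", call. = FALSE)
  }
  m
}

# Noise SD on the growth rate that makes the population correlation
# between equation-predicted and realized growth equal target_r.
calibrate_growth_noise <- function(eq, sd_d2, sd_d3, rho, target_r) {
  var_signal <- eq$coef_d2^2 * sd_d2^2 + eq$coef_d3^2 * sd_d3^2 +
    2 * eq$coef_d2 * eq$coef_d3 * rho * sd_d2 * sd_d3
  sqrt(var_signal * (1 / target_r^2 - 1))
}

#' Simulate an HNSCC-like study cohort
#'
#' Draws a per-patient 14-parameter diffusion profile anchored to the
#' published cohort distributions ([hnscc_reference_params()]), links the
#' true growth rate to D2 and D3 through the packaged prediction equation
#' plus Gaussian noise, and realizes two-timepoint lesion sizes via
#' [project_size()] with truncated-normal inter-scan durations
#' (mean 34.2, SD 4.15, range 25-43 days).
#'
#' The coefficients (adc, d, ddc, d_k, d2, d3) are drawn from a correlated
#' multivariate normal (block correlation `block_r` among the first five,
#' `d3_r` between d3 and each of them), truncated to positive values and to
#' the d2 > d3 ordering by resampling. Fractions f1, f2 are truncated
#' normals with f3 = 1 - f1 - f2; d_star and d1 are truncated normals kept
#' above their slow counterparts; alpha is truncated to (0, 1] and k to
#' (0, 3]. The growth-noise SD defaults to the value that makes the
#' population correlation between equation-predicted and realized growth
#' rates equal `target_r`.
#'
#' @param n Number of patients (>= 10).
#' @param seed Integer seed.
#' @param group Reference parameter set, `"discovery"` or `"validation"`.
#' @param eq Generating [growth_equation()] (default
#'   [hnscc_growth_equation()]).
#' @param target_r Population correlation between equation prediction and
#'   realized growth rate used to calibrate the growth noise (default
#'   0.74).
#' @param growth_noise_sd Override for the growth-noise SD (rate units);
#'   `NULL` (default) calibrates it from `target_r`; 0 gives noiseless
#'   rates.
#' @param rho_d2_d3,block_r Correlation defaults for the coefficient draw.
#' @param duration_mean,duration_sd,duration_range Inter-scan interval
#'   distribution in days.
#' @param curves Also synthesize one tri-exponential [signal_curve()] per
#'   patient from the drawn parameters (default `TRUE`).
#' @param snr,noise Signal simulation settings passed to
#'   [simulate_signal()] when `curves = TRUE`.
#' @return List of class `synthetic_cohort`: `cohort` (data frame with id,
#'   demographics, the 14 parameters, sizes, duration, growth_rate),
#'   `curves` (list of `signal_curve` or `NULL`), and `truth` (generator
#'   settings: equation, growth-noise SD, seed).
#' @export
simulate_cohort <- function(n = 55L, seed, group = "discovery",
                            eq = hnscc_growth_equation(),
                            target_r = 0.74, growth_noise_sd = NULL,
                            rho_d2_d3 = 0.45, block_r = 0.9,
                            duration_mean = 34.2, duration_sd = 4.15,
                            duration_range = c(25, 43),
                            curves = TRUE, snr = 100,
                            noise = c("rician", "gaussian", "none")) {
  noise <- match.arg(noise)
  n <- as.integer(n)
  if (n < 10L) stop("cohort simulation needs n >= 10", call. = FALSE)
  ref <- hnscc_reference_params(group)
  mu <- stats::setNames(ref$mean, ref$param)
  sg <- stats::setNames(ref$sd, ref$param)
  cm <- diffusion_cor_matrix(block_r, rho_d2_d3)
  if (is.null(growth_noise_sd)) {
    growth_noise_sd <- calibrate_growth_noise(
      eq, sg[["d2"]], sg[["d3"]], rho_d2_d3, target_r)
  }

  cohort <- with_seed(seed, {
    nm <- colnames(cm)
    sd_vec <- sg[nm]
    cov <- cm * (sd_vec %o% sd_vec)
    draw <- MASS::mvrnorm(n, mu[nm], cov)
    # enforce positivity and the d2 > d3 ordering by resampling
    bad <- which(apply(draw, 1L, function(r) any(r <= 0) || r["d2"] <= r["d3"]))
    while (length(bad) > 0L) {
      draw[bad, ] <- MASS::mvrnorm(length(bad), mu[nm], cov, empirical = FALSE)
      bad <- which(apply(draw, 1L, function(r) {
        any(r <= 0) || r["d2"] <= r["d3"]
      }))
    }
    co <- as.data.frame(draw)

    co$f1 <- rtruncnorm(n, mu[["f1"]], sg[["f1"]], 0.01, 0.5)
    co$f2 <- rtruncnorm(n, mu[["f2"]], sg[["f2"]], 0.01, 0.98 - co$f1)
    co$f3 <- 1 - co$f1 - co$f2
    co$f <- rtruncnorm(n, mu[["f"]], sg[["f"]], 0.01, 0.9)
    co$d_star <- pmax(rtruncnorm(n, mu[["d_star"]], sg[["d_star"]], 2, 100),
                      co$d * 1.5)
    co$d1 <- pmax(rtruncnorm(n, mu[["d1"]], sg[["d1"]], 3, 100),
                  co$d2 * 2)
    co$alpha <- rtruncnorm(n, mu[["alpha"]], sg[["alpha"]], 0.05, 1)
    co$k <- rtruncnorm(n, mu[["k"]], sg[["k"]], 0.01, 3)

    co$growth_rate <- predict_growth(eq, co$d2, co$d3) +
      stats::rnorm(n, 0, growth_noise_sd)
    co$growth_rate <- pmax(co$growth_rate, 50)  # physical floor

    co$duration_days <- round(rtruncnorm(n, duration_mean, duration_sd,
                                         duration_range[1L],
                                         duration_range[2L]))
    co$size_pre_cm2 <- rtruncnorm(n, mu[["size_pre"]], sg[["size_pre"]],
                                  2, 25)
    co$size_post_cm2 <- project_size(co$size_pre_cm2, co$growth_rate,
                                     co$duration_days)

    co$id <- sprintf("P%03d", seq_len(n))
    co$age <- round(rtruncnorm(n, 62.5, 8, 47, 80))
    co$sex <- stats::rbinom(n, 1, 48 / 55)           # male = 0 coding below
    co$sex <- ifelse(co$sex == 1, "male", "female")
    co$site <- sample(c("oral cavity", "oropharynx", "hypopharynx",
                        "nasal cavity", "paranasal sinus"),
                      n, replace = TRUE,
                      prob = c(16, 16, 8, 2, 13) / 55)
    co$t_stage <- sample(c("T2", "T3", "T4a", "T4b"), n, replace = TRUE,
                         prob = c(11, 14, 26, 4) / 55)
    co$n_stage <- sample(c("N0", "N1", "N2"), n, replace = TRUE,
                         prob = c(26, 8, 21) / 55)
    co$smoking <- sample(c("smoker", "non-smoker"), n, replace = TRUE,
                         prob = c(50, 5) / 55)
    co$alcohol <- sample(c("occasional or non-drinker", "moderate", "heavy"),
                         n, replace = TRUE, prob = c(11, 20, 24) / 55)
    cols <- c("id", "age", "sex", "site", "t_stage", "n_stage", "smoking",
              "alcohol", "adc", "f", "d_star", "d", "f1", "f2", "f3",
              "d1", "d2", "d3", "alpha", "ddc", "d_k", "k",
              "size_pre_cm2", "size_post_cm2", "duration_days",
              "growth_rate")
    co[cols]
  })

  curve_list <- NULL
  if (curves) {
    curve_list <- lapply(seq_len(n), function(i) {
      p <- triexp_params(cohort$f1[i], cohort$f2[i], cohort$f3[i],
                         cohort$d1[i], cohort$d2[i], cohort$d3[i])
      sub_seed <- as.integer((as.numeric(seed) * 1000 + i) %%
                               .Machine$integer.max)
      simulate_signal("triexp", p, s0 = 1000, snr = snr, noise = noise,
                      seed = if (noise == "none") NULL else sub_seed)
    })
    names(curve_list) <- cohort$id
  }

  structure(list(cohort = cohort, curves = curve_list,
                 truth = list(equation = eq,
                              growth_noise_sd = growth_noise_sd,
                              target_r = target_r, group = group,
                              seed = seed)),
            class = "synthetic_cohort")
}

#' Simulate survival outcomes linked to the growth rate
#'
#' Exponential event times whose log-hazard is affine in the standardized
#' growth rate, with uniform administrative censoring inside the given
#' follow-up window (defaults: 8-42 months for OS-like, use
#' `follow_up = c(4, 42)` for PFS-like outcomes). `link = 0` gives
#' null-calibrated outcomes independent of the growth rate.
#'
#' @param growth_rate Per-patient growth rates.
#' @param seed Integer seed.
#' @param link Log-hazard increase per SD of growth rate (default 0.5).
#' @param median_months Baseline median event time at the mean growth rate
#'   (default 24).
#' @param follow_up Censoring window in months (default `c(8, 42)`).
#' @return Data frame with columns `months` and `event`.
#' @export
simulate_survival <- function(growth_rate, seed, link = 0.5,
                              median_months = 24, follow_up = c(8, 42)) {
  stopifnot(length(follow_up) == 2L)
  if (follow_up[2L] <= 0) {
    stop("degenerate censoring horizon: follow_up must extend past 0",
         call. = FALSE)
  }
  n <- length(growth_rate)
  z <- if (stats::sd(growth_rate) == 0) rep(0, n) else {
    (growth_rate - mean(growth_rate)) / stats::sd(growth_rate)
  }
  lambda0 <- log(2) / median_months
  with_seed(seed, {
    tt <- stats::rexp(n, rate = lambda0 * exp(link * z))
    cc <- stats::runif(n, follow_up[1L], follow_up[2L])
    data.frame(months = pmin(tt, cc), event = as.integer(tt <= cc))
  })
}

#' Simulate a rater pair for agreement checks
#'
#' Adds independent Gaussian reading error to a vector of true values for
#' two raters; the expected ICC(2,1) is
#' var(true) / (var(true) + rater_sd^2).
#'
#' @param true_values True per-subject values.
#' @param rater_sd Reading-error SD (>= 0).
#' @param seed Integer seed.
#' @return n x 2 matrix of ratings.
#' @export
simulate_rater_pair <- function(true_values, rater_sd, seed) {
  if (rater_sd < 0) stop("rater_sd must be >= 0", call. = FALSE)
  n <- length(true_values)
  with_seed(seed, {
    cbind(rater1 = true_values + stats::rnorm(n, 0, rater_sd),
          rater2 = true_values + stats::rnorm(n, 0, rater_sd))
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "patients (",
      x$truth$group, "reference distributions )\n")
  cat(sprintf("  generating equation: D2 %.3g, D3 %.3g, intercept %.4g\n",
              x$truth$equation$coef_d2, x$truth$equation$coef_d3,
              x$truth$equation$intercept))
  cat(sprintf("  growth-noise SD %.3g (target r %.2f); seed %d\n",
              x$truth$growth_noise_sd, x$truth$target_r, x$truth$seed))
  invisible(x)
}
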