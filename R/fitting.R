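# Segmented (stepwise) and joint constrained least-squares fitting of the
# five diffusion models to ROI-mean signal curves.
#
# Stepwise procedures:
#   bi-exponential, two steps:  (1) log-linear mono fit on b > 200 -> D;
#     (2) bounded Levenberg-Marquardt fit of (f, D*) over all b-values with
#     D held fixed and S0 pinned to the measured b = 0 signal.
#   tri-exponential, three steps: (1) log-linear mono fit on
#     b in {800, 1000, 2000} -> D3; (2) two-component fit on b >= 200 with
#     D3 fixed -> D2; (3) fit of (f1, f2, D1) over all b with D2, D3 fixed,
#     f3 = 1 - f1 - f2 and S0 pinned.
# Joint fits refine all free parameters simultaneously (fraction-sum
# constraint kept by parameterizing the free fractions) and serve as the
# reference estimates for noiseless round-trip checks.

#' Fitting configuration
#'
#' Collects every tunable of the model fits: the b-value subsets each
#' procedure uses, optimizer box bounds, initial values, and convergence
#' tolerances for the bounded Levenberg-Marquardt optimizer.
#'
#' The defaults encode the acquisition-matched choices used throughout:
#' mono/SEM/DKI are fitted on the six tissue-diffusion b-values
#' (0, 200, 400, 800, 1000, 2000 s/mm^2, excluding the perfusion-sensitive
#' low-b points); the bi-exponential step 1 uses b > 200 strictly; the
#' tri-exponential step 1 uses b in {800, 1000, 2000} and step 2 uses
#' b >= 200.
#'
#' @param subset_mono,subset_sem,subset_dki b-values used by the
#'   mono-exponential, stretched-exponential and kurtosis fits.
#' @param biexp_step1_min b-values strictly greater than this enter the
#'   bi-exponential step-1 mono fit (default 200).
#' @param triexp_step1_b b-values of the tri-exponential step-1 mono fit.
#' @param triexp_step2_min b-values greater than or equal to this enter the
#'   tri-exponential step-2 fit (default 200).
#' @param d_bounds Lower/upper box bounds for every diffusion coefficient,
#'   in 1e-3 mm^2/s.
#' @param k_bounds Bounds for the kurtosis K.
#' @param alpha_bounds Bounds for the stretching exponent alpha.
#' @param init_d_star,init_alpha,init_k,init_d1 Optimizer starting values.
#' @param ftol,ptol Cost and parameter convergence tolerances.
#' @param maxfev Maximum residual-function evaluations.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(subset_mono = c(0, 200, 400, 800, 1000, 2000),
                       subset_sem = subset_mono,
                       subset_dki = subset_mono,
                       biexp_step1_min = 200,
                       triexp_step1_b = c(800, 1000, 2000),
                       triexp_step2_min = 200,
                       d_bounds = c(1e-3, 500),
                       k_bounds = c(0, 3),
                       alpha_bounds = c(1e-6, 1),
                       init_d_star = 20,
                       init_alpha = 0.8,
                       init_k = 0.7,
                       init_d1 = 20,
                       ftol = 1e-10,
                       ptol = 1e-10,
                       maxfev = 5000L) {
  structure(list(subset_mono = subset_mono, subset_sem = subset_sem,
                 subset_dki = subset_dki,
                 biexp_step1_min = biexp_step1_min,
                 triexp_step1_b = triexp_step1_b,
                 triexp_step2_min = triexp_step2_min,
                 d_bounds = d_bounds, k_bounds = k_bounds,
                 alpha_bounds = alpha_bounds,
                 init_d_star = init_d_star, init_alpha = init_alpha,
                 init_k = init_k, init_d1 = init_d1,
                 ftol = ftol, ptol = ptol, maxfev = as.integer(maxfev)),
            class = "fit_config")
}

# Bounded LM least squares; returns par, residual norm and convergence flag.
lm_fit <- function(resid_fn, par, lower, upper, config) {
  fit <- minpack.lm::nls.lm(
    par = par, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = config$ftol,
                                         ptol = config$ptol,
                                         maxfev = config$maxfev,
                                         maxiter = 1000L))
  list(par = stats::coef(fit),
       residual = sqrt(sum(fit$fvec^2)),
       converged = fit$info %in% 1:4,
       info = fit$info)
}

# Select curve points whose b-values lie in `b_keep` (exact match).
curve_points <- function(curve, b_keep) {
  idx <- match(b_keep, curve$scheme$b_values)
  if (anyNA(idx)) {
    stop("requested b-values not in the curve's scheme: ",
         paste(b_keep[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  list(b = curve$scheme$b_values[idx], s = curve$signal[idx])
}

# Log-linear (free-amplitude) mono-exponential fit; exact on noiseless
# mono input. Returns adc (1e-3 mm^2/s) and amplitude.
loglinear_mono <- function(b, s) {
  if (any(s <= 0)) stop("non-positive signals cannot be log-fitted",
                        call. = FALSE)
  if (length(unique(b)) < 2L) {
    stop("mono-exponential fit needs >= 2 distinct b-values", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, b), log(s))
  list(adc = max(0, -fit$coefficients[[2L]] / DC_SCALE),
       amplitude = exp(fit$coefficients[[1L]]))
}

new_fit <- function(params, residual, converged, class, extra = list()) {
  structure(c(params, list(residual = residual, converged = converged),
              extra),
            class = c(class, "dwi_fit"))
}

#' @export
print.dwi_fit <- function(x, ...) {
  nm <- setdiff(names(x), c("residual", "converged", "steps"))
  vals <- unlist(x[nm])
  cat(class(x)[1L], "\n")
  print(round(vals, 5))
  cat("residual norm:", format(x$residual, digits = 4),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Mono-exponential (ADC) fit
#'
#' Least-squares ADC estimate by log-linear regression with a free
#' amplitude, on the six tissue-diffusion b-values by default. Exact on
#' noiseless mono-exponential input.
#'
#' @param curve A [signal_curve()].
#' @param subset b-values to use (default from `config`).
#' @param config A [fit_config()].
#' @return A `mono_fit`: `adc` (1e-3 mm^2/s) plus `residual` (norm of the
#'   natural-scale residuals) and `converged`.
#' @export
fit_mono <- function(curve, subset = NULL, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  if (is.null(subset)) subset <- intersect(config$subset_mono,
                                           curve$scheme$b_values)
  pts <- curve_points(curve, subset)
  ll <- loglinear_mono(pts$b, pts$s)
  res <- sqrt(sum((ll$amplitude * exp(-pts$b * ll$adc * DC_SCALE) - pts$s)^2))
  new_fit(list(adc = ll$adc, amplitude = ll$amplitude), res, TRUE, "mono_fit")
}

#' Stretched-exponential (SEM) fit
#'
#' Bounded Levenberg-Marquardt fit of the heterogeneity exponent alpha and
#' distributed diffusion coefficient DDC on the six tissue-diffusion
#' b-values, with S0 pinned to the measured b = 0 signal.
#'
#' @inheritParams fit_mono
#' @return A `sem_fit` with `alpha`, `ddc`, `residual`, `converged`.
#' @export
fit_sem <- function(curve, subset = NULL, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  if (is.null(subset)) subset <- intersect(config$subset_sem,
                                           curve$scheme$b_values)
  pts <- curve_points(curve, subset)
  if (length(pts$b) < 3L) {
    stop("SEM fit needs >= 3 b-values", call. = FALSE)
  }
  s0 <- s0(curve)
  ddc0 <- loglinear_mono(pts$b, pts$s)$adc
  fit <- lm_fit(function(p) {
    s0 * exp(-(pts$b * p[["ddc"]] * DC_SCALE)^p[["alpha"]]) - pts$s
  }, par = c(alpha = config$init_alpha, ddc = max(ddc0, config$d_bounds[1L])),
  lower = c(config$alpha_bounds[1L], config$d_bounds[1L]),
  upper = c(config$alpha_bounds[2L], config$d_bounds[2L]),
  config = config)
  new_fit(list(alpha = fit$par[["alpha"]], ddc = fit$par[["ddc"]]),
          fit$residual, fit$converged, "sem_fit")
}

#' Diffusion kurtosis (DKI) fit
#'
#' Bounded Levenberg-Marquardt fit of the kurtosis-corrected diffusion
#' coefficient Dk and kurtosis K on the six tissue-diffusion b-values, S0
#' pinned to the measured b = 0 signal.
#'
#' @inheritParams fit_mono
#' @return A `dki_fit` with `d_k`, `k`, `residual`, `converged`.
#' @export
fit_dki <- function(curve, subset = NULL, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  if (is.null(subset)) subset <- intersect(config$subset_dki,
                                           curve$scheme$b_values)
  pts <- curve_points(curve, subset)
  if (length(pts$b) < 3L) {
    stop("DKI fit needs >= 3 b-values", call. = FALSE)
  }
  s0 <- s0(curve)
  dk0 <- loglinear_mono(pts$b, pts$s)$adc
  fit <- lm_fit(function(p) {
    bd <- pts$b * p[["d_k"]] * DC_SCALE
    s0 * exp(-bd + bd^2 * p[["k"]] / 6) - pts$s
  }, par = c(d_k = max(dk0, config$d_bounds[1L]), k = config$init_k),
  lower = c(config$d_bounds[1L], config$k_bounds[1L]),
  upper = c(config$d_bounds[2L], config$k_bounds[2L]),
  config = config)
  new_fit(list(d_k = fit$par[["d_k"]], k = fit$par[["k"]]),
          fit$residual, fit$converged, "dki_fit")
}

#' Two-step (segmented) bi-exponential IVIM fit
#'
#' Step 1 estimates the true diffusion coefficient D by a free-amplitude
#' log-linear mono fit restricted to b > 200 s/mm^2, where the
#' pseudo-diffusion component has decayed away. Step 2 fits the perfusion
#' fraction f and pseudo-diffusion coefficient D* over all b-values with D
#' held fixed and S0 pinned to the b = 0 signal.
#'
#' @inheritParams fit_mono
#' @return A `biexp_fit` with `f`, `d_star`, `d`, `residual` (all-b natural
#'   scale), `converged`, and a `steps` list recording the step-1 result.
#' @export
fit_biexp_twostep <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  b <- curve$scheme$b_values
  high <- b[b > config$biexp_step1_min]
  if (length(high) < 2L) {
    stop("need >= 2 b-values above ", config$biexp_step1_min,
         " for the step-1 mono fit", call. = FALSE)
  }
  pts <- curve_points(curve, high)
  step1 <- loglinear_mono(pts$b, pts$s)
  d_fix <- step1$adc
  s0 <- s0(curve)
  # amplitude of the slow compartment extrapolated to b = 0 gives the
  # perfusion-fraction starting value
  f0 <- min(max(1 - step1$amplitude / s0, 0.01), 0.6)
  fit <- lm_fit(function(p) {
    s0 * (p[["f"]] * exp(-b * p[["d_star"]] * DC_SCALE) +
            (1 - p[["f"]]) * exp(-b * d_fix * DC_SCALE)) - curve$signal
  }, par = c(f = f0, d_star = max(config$init_d_star, d_fix)),
  lower = c(0, d_fix), upper = c(1, config$d_bounds[2L]),
  config = config)
  new_fit(list(f = fit$par[["f"]], d_star = fit$par[["d_star"]], d = d_fix),
          fit$residual, fit$converged, "biexp_fit",
          extra = list(steps = list(step1 = step1)))
}

#' Joint bi-exponential fit
#'
#' Refines all three IVIM parameters simultaneously by bounded
#' Levenberg-Marquardt over every b-value (S0 pinned), typically
#' initialized from [fit_biexp_twostep()]. On noiseless model-true input
#' this reaches the generating parameters (residual < 1e-10).
#'
#' @param curve A [signal_curve()].
#' @param init A `biexp_fit` or [biexp_params()] starting point; default is
#'   the two-step fit.
#' @param config A [fit_config()].
#' @return A `biexp_fit`.
#' @export
fit_biexp_joint <- function(curve, init = NULL, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  if (is.null(init)) init <- fit_biexp_twostep(curve, config)
  b <- curve$scheme$b_values
  s0 <- s0(curve)
  fit <- lm_fit(function(p) {
    s0 * (p[["f"]] * exp(-b * p[["d_star"]] * DC_SCALE) +
            (1 - p[["f"]]) * exp(-b * p[["d"]] * DC_SCALE)) - curve$signal
  }, par = c(f = init$f, d_star = init$d_star, d = init$d),
  lower = c(0, config$d_bounds[1L], config$d_bounds[1L]),
  upper = c(1, config$d_bounds[2L], config$d_bounds[2L]),
  config = config)
  p <- fit$par
  swapped <- FALSE
  if (p[["d_star"]] < p[["d"]]) {  # relabel: components are exchangeable
    p <- c(f = 1 - p[["f"]], d_star = p[["d"]], d = p[["d_star"]])
    swapped <- TRUE
  }
  new_fit(list(f = p[["f"]], d_star = p[["d_star"]], d = p[["d"]]),
          fit$residual, fit$converged, "biexp_fit",
          extra = list(steps = list(relabelled = swapped)))
}

#' Three-step (segmented) tri-exponential fit
#'
#' Step 1 estimates the slow diffusion coefficient D3 by a free-amplitude
#' log-linear mono fit on b in {800, 1000, 2000} s/mm^2. Step 2 fits a
#' two-component model (free amplitude, relative fraction and D2; D3
#' fixed) on b >= 200. Step 3 fits D1 and the fractions f1, f2
#' (f3 = 1 - f1 - f2) over all b-values with D2 and D3 held fixed and S0
#' pinned.
#'
#' The step-1 D3 carries a known upward bias on tri-exponential input
#' because the b >= 800 window still contains intermediate-compartment
#' signal; use [fit_triexp_joint()] initialized from this fit when an
#' unbiased noiseless round-trip is required.
#'
#' @inheritParams fit_mono
#' @return A `triexp_fit` with `f1`, `f2`, `f3`, `d1`, `d2`, `d3`,
#'   `residual`, `converged` and a `steps` list with intermediate results.
#' @export
fit_triexp_threestep <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  b <- curve$scheme$b_values
  s0 <- s0(curve)

  # step 1: D3 from the highest b-values
  p1 <- curve_points(curve, intersect(config$triexp_step1_b, b))
  if (length(p1$b) < 2L) stop("step 1 needs >= 2 high b-values", call. = FALSE)
  step1 <- loglinear_mono(p1$b, p1$s)
  d3 <- step1$adc

  # step 2: D2 from a two-component fit on b >= 200 with D3 fixed
  mid_b <- b[b >= config$triexp_step2_min]
  p2 <- curve_points(curve, mid_b)
  if (length(p2$b) < 4L) stop("step 2 needs >= 4 b-values", call. = FALSE)
  a0 <- min(step1$amplitude * 1.2, s0)
  fit2 <- lm_fit(function(p) {
    p[["amp"]] * (p[["w"]] * exp(-p2$b * p[["d2"]] * DC_SCALE) +
                    (1 - p[["w"]]) * exp(-p2$b * d3 * DC_SCALE)) - p2$s
  }, par = c(amp = a0, w = 0.3, d2 = max(2 * d3, 1)),
  lower = c(1e-9, 0, d3), upper = c(10 * s0, 1, config$d_bounds[2L]),
  config = config)
  d2 <- fit2$par[["d2"]]

  # step 3: D1 and fractions on all b with D2, D3 fixed, S0 pinned
  amp2 <- fit2$par[["amp"]]
  f1_0 <- min(max(1 - amp2 / s0, 0.02), 0.5)
  f2_0 <- min(max(fit2$par[["w"]] * amp2 / s0, 0.02), 1 - f1_0)
  fit3 <- lm_fit(function(p) {
    s0 * (p[["f1"]] * exp(-b * p[["d1"]] * DC_SCALE) +
            p[["f2"]] * exp(-b * d2 * DC_SCALE) +
            (1 - p[["f1"]] - p[["f2"]]) * exp(-b * d3 * DC_SCALE)) -
      curve$signal
  }, par = c(f1 = f1_0, f2 = f2_0, d1 = max(config$init_d1, d2)),
  lower = c(0, 0, d2), upper = c(1, 1, config$d_bounds[2L]),
  config = config)

  f1 <- fit3$par[["f1"]]; f2 <- fit3$par[["f2"]]
  f3 <- 1 - f1 - f2
  ok <- fit3$converged && f3 >= -1e-9 && d3 <= d2 && d2 <= fit3$par[["d1"]]
  if (f3 < 0) {  # renormalize a marginal constraint violation, flag it
    f3 <- 0
    tot <- f1 + f2
    f1 <- f1 / tot; f2 <- f2 / tot
  }
  new_fit(list(f1 = f1, f2 = f2, f3 = f3,
               d1 = fit3$par[["d1"]], d2 = d2, d3 = d3),
          fit3$residual, ok, "triexp_fit",
          extra = list(steps = list(step1 = step1, step2 = fit2$par)))
}

#' Joint constrained tri-exponential fit
#'
#' Refines all six tri-exponential parameters simultaneously (f3 implied by
#' the fraction-sum constraint, S0 pinned) by bounded Levenberg-Marquardt,
#' typically initialized from [fit_triexp_threestep()]. The compartment
#' ordering d1 >= d2 >= d3 is restored by relabeling if the optimizer
#' exchanges components.
#'
#' @param curve A [signal_curve()].
#' @param init A `triexp_fit` or [triexp_params()] starting point; default
#'   is the three-step fit.
#' @param config A [fit_config()].
#' @return A `triexp_fit`.
#' @export
fit_triexp_joint <- function(curve, init = NULL, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  if (is.null(init)) init <- fit_triexp_threestep(curve, config)
  b <- curve$scheme$b_values
  s0 <- s0(curve)
  fit <- lm_fit(function(p) {
    s0 * (p[["f1"]] * exp(-b * p[["d1"]] * DC_SCALE) +
            p[["f2"]] * exp(-b * p[["d2"]] * DC_SCALE) +
            (1 - p[["f1"]] - p[["f2"]]) * exp(-b * p[["d3"]] * DC_SCALE)) -
      curve$signal
  }, par = c(f1 = init$f1, f2 = init$f2,
             d1 = init$d1, d2 = init$d2, d3 = init$d3),
  lower = c(0, 0, rep(config$d_bounds[1L], 3)),
  upper = c(1, 1, rep(config$d_bounds[2L], 3)),
  config = config)
  p <- fit$par
  f <- c(p[["f1"]], p[["f2"]], 1 - p[["f1"]] - p[["f2"]])
  d <- c(p[["d1"]], p[["d2"]], p[["d3"]])
  ord <- order(d, decreasing = TRUE)  # restore compartment labels
  f <- f[ord]; d <- d[ord]
  ok <- fit$converged && all(f >= -1e-9)
  f <- pmax(f, 0); f <- f / sum(f)
  new_fit(list(f1 = f[1L], f2 = f[2L], f3 = f[3L],
               d1 = d[1L], d2 = d[2L], d3 = d[3L]),
          fit$residual, ok, "triexp_fit",
          extra = list(steps = list(relabelled = !identical(ord, 1:3))))
}

#' Fit all five diffusion models to one curve
#'
#' Runs the mono-exponential, bi-exponential (two-step, then joint
#' refinement when `refine = TRUE`), tri-exponential (three-step, then
#' joint refinement), stretched-exponential and kurtosis fits with their
#' acquisition-matched b-value subsets, and collects the 14 parameters with
#' per-model diagnostics.
#'
#' @param curve A [signal_curve()] on the 12-b scheme (or any scheme rich
#'   enough for every sub-fit).
#' @param config A [fit_config()].
#' @param refine Refine the segmented bi-/tri-exponential estimates with
#'   joint constrained fits (default `TRUE`); the segmented results are
#'   kept in the `stepwise` element either way.
#' @return A `diffusion_parameter_set`: list with elements `mono`, `biexp`,
#'   `triexp`, `sem`, `dki` (each a `dwi_fit`), `stepwise` (segmented
#'   bi/tri fits), and `snr` (per-b SNR or `NA` when no noise SD is
#'   recorded). Use [parameter_vector()] for the flat 14-parameter form.
#' @export
fit_all_models <- function(curve, config = fit_config(), refine = TRUE) {
  stopifnot(inherits(curve, "signal_curve"))
  mono <- fit_mono(curve, config = config)
  sem <- fit_sem(curve, config = config)
  dki <- fit_dki(curve, config = config)
  bi_step <- fit_biexp_twostep(curve, config)
  tri_step <- fit_triexp_threestep(curve, config)
  biexp <- if (refine) fit_biexp_joint(curve, bi_step, config) else bi_step
  triexp <- if (refine) fit_triexp_joint(curve, tri_step, config) else tri_step
  snr <- if (is.null(curve$noise_sd)) {
    stats::setNames(rep(NA_real_, length(curve$signal)),
                    curve$scheme$b_values)
  } else {
    compute_snr(curve)
  }
  structure(list(mono = mono, biexp = biexp, triexp = triexp,
                 sem = sem, dki = dki,
                 stepwise = list(biexp = bi_step, triexp = tri_step),
                 snr = snr),
            class = "diffusion_parameter_set")
}

#' @rdname fit_all_models
#' @param pset A `diffusion_parameter_set`.
#' @export
parameter_vector <- function(pset) {
  stopifnot(inherits(pset, "diffusion_parameter_set"))
  c(adc = pset$mono$adc,
    f = pset$biexp$f, d_star = pset$biexp$d_star, d = pset$biexp$d,
    f1 = pset$triexp$f1, f2 = pset$triexp$f2, f3 = pset$triexp$f3,
    d1 = pset$triexp$d1, d2 = pset$triexp$d2, d3 = pset$triexp$d3,
    alpha = pset$sem$alpha, ddc = pset$sem$ddc,
    d_k = pset$dki$d_k, k = pset$dki$k)
}

#' @export
print.diffusion_parameter_set <- function(x, ...) {
  cat("Diffusion parameter set (14 parameters)\n")
  print(round(parameter_vector(x), 4))
  conv <- vapply(x[c("mono", "biexp", "triexp", "sem", "dki")],
                 `[[`, logical(1L), "converged")
  cat("converged:", paste(names(conv)[!conv], collapse = " "),
      if (all(conv)) "all models" else "(listed models NOT converged)", "\n")
  invisible(x)
}
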