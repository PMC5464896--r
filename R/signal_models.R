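# Forward signal equations of the five diffusion models.
#
# Unit convention (used package-wide): all diffusion coefficients are
# stored and reported in 1e-3 mm^2/s, the convention in which fitted values
# for soft tissue are O(1). b-values are in s/mm^2, so every forward
# evaluation multiplies by 1e-3 to return to SI-consistent b*D products.

DC_SCALE <- 1e-3

check_b_s0 <- function(b, s0) {
  if (any(!is.finite(b)) || any(b < 0)) {
    stop("b-values must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be > 0", call. = FALSE)
}

#' Diffusion model parameter records
#'
#' Constructors for the parameter sets of the five diffusion signal models.
#' All diffusion coefficients are in 1e-3 mm^2/s; fractions, `alpha` and `k`
#' are unitless. Each constructor validates the model's physical
#' constraints.
#'
#' * `mono_params()`: apparent diffusion coefficient `adc >= 0`.
#' * `biexp_params()`: IVIM perfusion fraction `f` in \[0, 1\],
#'   pseudo-diffusion `d_star` and true diffusion `d` with
#'   `d_star >= d >= 0`.
#' * `triexp_params()`: three fractions summing to 1 with ordered
#'   coefficients `d1 >= d2 >= d3 >= 0` (perfusion-related, intermediate,
#'   slow compartments).
#' * `sem_params()`: stretched-exponential heterogeneity exponent
#'   `alpha` in (0, 1\] and distributed diffusion coefficient `ddc >= 0`.
#' * `dki_params()`: kurtosis-corrected diffusion coefficient `d_k >= 0`
#'   and kurtosis `k >= 0`.
#'
#' @param adc,f,d_star,d,f1,f2,f3,d1,d2,d3,alpha,ddc,d_k,k Model parameters
#'   (see above).
#' @return A classed list holding the validated parameters.
#' @name diffusion_params
NULL

#' @rdname diffusion_params
#' @export
mono_params <- function(adc) {
  if (!is.finite(adc) || adc < 0) stop("adc must be >= 0", call. = FALSE)
  structure(list(adc = adc), class = "mono_params")
}

#' @rdname diffusion_params
#' @export
biexp_params <- function(f, d_star, d) {
  if (!is.finite(f) || f < 0 || f > 1) {
    stop("perfusion fraction f must lie in [0, 1]", call. = FALSE)
  }
  if (d < 0 || d_star < d) {
    stop("need d_star >= d >= 0", call. = FALSE)
  }
  structure(list(f = f, d_star = d_star, d = d), class = "biexp_params")
}

#' @rdname diffusion_params
#' @export
triexp_params <- function(f1, f2, f3, d1, d2, d3) {
  fr <- c(f1, f2, f3)
  if (any(!is.finite(fr)) || any(fr < 0)) {
    stop("fractions must be finite and >= 0", call. = FALSE)
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("fractions f1 + f2 + f3 must sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  if (d3 < 0 || d2 < d3 || d1 < d2) {
    stop("need d1 >= d2 >= d3 >= 0", call. = FALSE)
  }
  structure(list(f1 = f1, f2 = f2, f3 = f3, d1 = d1, d2 = d2, d3 = d3),
            class = "triexp_params")
}

#' @rdname diffusion_params
#' @export
sem_params <- function(alpha, ddc) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (ddc < 0) stop("ddc must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, ddc = ddc), class = "sem_params")
}

#' @rdname diffusion_params
#' @export
dki_params <- function(d_k, k) {
  if (d_k < 0) stop("d_k must be >= 0", call. = FALSE)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  structure(list(d_k = d_k, k = k), class = "dki_params")
}

#' Forward diffusion signal models
#'
#' Evaluate the noiseless ROI-mean signal of each diffusion model at one or
#' more b-values. All functions return `s0` at b = 0 and are vectorized
#' over `b`.
#'
#' * `mono_signal()`: \eqn{S(b) = S_0 e^{-b \cdot ADC}}
#' * `biexp_signal()` (IVIM): \eqn{S(b) = S_0 (f e^{-b D^*} + (1-f) e^{-b D})}
#' * `triexp_signal()`: \eqn{S(b) = S_0 \sum_i f_i e^{-b D_i}}
#' * `dki_signal()`: \eqn{S(b) = S_0 \exp(-b D_k + \frac{1}{6} b^2 D_k^2 K)}
#' * `sem_signal()`: \eqn{S(b) = S_0 \exp(-(b \cdot DDC)^\alpha)}
#'
#' Diffusion coefficients in the parameter records are in 1e-3 mm^2/s and
#' are converted to mm^2/s internally before multiplying by b (s/mm^2).
#'
#' @param b b-value(s) in s/mm^2, >= 0.
#' @param s0 Signal at b = 0, > 0.
#' @param p Parameter record from the matching constructor (see
#'   [diffusion_params]); a plain list with the same fields is accepted and
#'   validated.
#' @return Numeric vector of signal intensities, same length as `b`.
#' @examples
#' mono_signal(1000, 1, mono_params(adc = 0.95))
#' biexp_signal(c(0, 1000), 1, biexp_params(f = 0.16, d_star = 19.8, d = 0.74))
#' @name signal_models
NULL

#' @rdname signal_models
#' @export
mono_signal <- function(b, s0, p) {
  if (!inherits(p, "mono_params")) p <- do.call(mono_params, p["adc"])
  check_b_s0(b, s0)
  s0 * exp(-b * p$adc * DC_SCALE)
}

#' @rdname signal_models
#' @export
biexp_signal <- function(b, s0, p) {
  if (!inherits(p, "biexp_params")) p <- do.call(biexp_params, p[c("f", "d_star", "d")])
  check_b_s0(b, s0)
  s0 * (p$f * exp(-b * p$d_star * DC_SCALE) +
          (1 - p$f) * exp(-b * p$d * DC_SCALE))
}

#' @rdname signal_models
#' @export
triexp_signal <- function(b, s0, p) {
  if (!inherits(p, "triexp_params")) {
    p <- do.call(triexp_params, p[c("f1", "f2", "f3", "d1", "d2", "d3")])
  }
  check_b_s0(b, s0)
  s0 * (p$f1 * exp(-b * p$d1 * DC_SCALE) +
          p$f2 * exp(-b * p$d2 * DC_SCALE) +
          p$f3 * exp(-b * p$d3 * DC_SCALE))
}

#' @rdname signal_models
#' @export
dki_signal <- function(b, s0, p) {
  if (!inherits(p, "dki_params")) p <- do.call(dki_params, p[c("d_k", "k")])
  check_b_s0(b, s0)
  bd <- b * p$d_k * DC_SCALE
  s0 * exp(-bd + bd^2 * p$k / 6)
}

#' @rdname signal_models
#' @export
sem_signal <- function(b, s0, p) {
  if (!inherits(p, "sem_params")) p <- do.call(sem_params, p[c("alpha", "ddc")])
  check_b_s0(b, s0)
  s0 * exp(-(b * p$ddc * DC_SCALE)^p$alpha)
}

# Dispatch used by the simulator: evaluate any of the five models by name.
model_signal <- function(model, b, s0, p) {
  switch(model,
         mono   = mono_signal(b, s0, p),
         biexp  = biexp_signal(b, s0, p),
         triexp = triexp_signal(b, s0, p),
         dki    = dki_signal(b, s0, p),
         sem    = sem_signal(b, s0, p),
         stop("unknown model: ", model, call. = FALSE))
}
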