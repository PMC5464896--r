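#' Directly measured tumor growth rate
#'
#' The growth rate is the projected 30-day size ratio scaled so that the
#' size at the first scan is 100: from two same-modality scans,
#' \eqn{Size_{post} = Size_{pre} \cdot (Growth/100)^{duration/30}}, so
#' `growth_rate()` returns \eqn{100 (Size_{post}/Size_{pre})^{30/duration}}.
#' A value of 100 means no growth over 30 days; 110 means 10% growth.
#' The rate is invariant to the size unit (cm^2 vs mm^2).
#'
#' @param size_pre,size_post Lesion areas at the first and second scans
#'   (cm^2; any common unit), > 0.
#' @param duration Days between the two scans, > 0.
#' @return The 30-day growth rate (no-growth = 100).
#' @examples
#' growth_rate(100, 121, 60)  # 110: 10% growth per 30 days
#' @export
growth_rate <- function(size_pre, size_post, duration) {
  if (any(!is.finite(size_pre)) || any(size_pre <= 0) ||
      any(!is.finite(size_post)) || any(size_post <= 0)) {
    stop("lesion sizes must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stop("duration must be finite and > 0", call. = FALSE)
  }
  100 * (size_post / size_pre)^(30 / duration)
}

#' @rdname growth_rate
#' @param rate A growth rate on the no-growth = 100 scale, > 0.
#' @return `project_size()` returns the projected lesion size after
#'   `duration` days; it is the exact inverse of [growth_rate()].
#' @examples
#' project_size(100, 110, 60)  # 121
#' @export
project_size <- function(size_pre, rate, duration) {
  if (any(!is.finite(size_pre)) || any(size_pre <= 0)) {
    stop("size_pre must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stop("rate must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stop("duration must be finite and > 0", call. = FALSE)
  }
  size_pre * (rate / 100)^(duration / 30)
}

#' Growth-rate prediction equation
#'
#' An affine prediction of the 30-day tumor growth rate from the
#' tri-exponential intermediate (D2) and slow (D3) diffusion coefficients:
#' \deqn{\widehat{Growth} = intercept + coef_{D2} D_2 + coef_{D3} D_3}
#' with the coefficients expressed per 1e-3 mm^2/s (the package-wide unit
#' for diffusion coefficients). `hnscc_growth_equation()` returns the
#' published HNSCC equation, whose coefficients are -43.3 and -91.2 per
#' 1e-3 mm^2/s with intercept 227.5: lower intermediate and slow diffusion
#' (denser, faster-growing tumors) predict a higher growth rate.
#'
#' @param coef_d2,coef_d3 Slopes in rate units per 1e-3 mm^2/s.
#' @param intercept Intercept in rate units.
#' @return An object of class `growth_equation`.
#' @examples
#' eq <- hnscc_growth_equation()
#' predict_growth(eq, d2 = 0.93, d3 = 0.63)
#' @export
growth_equation <- function(coef_d2, coef_d3, intercept) {
  stopifnot(is.finite(coef_d2), is.finite(coef_d3), is.finite(intercept))
  structure(list(coef_d2 = coef_d2, coef_d3 = coef_d3,
                 intercept = intercept),
            class = "growth_equation")
}

#' @rdname growth_equation
#' @export
hnscc_growth_equation <- function() {
  growth_equation(coef_d2 = -43.3, coef_d3 = -91.2, intercept = 227.5)
}

#' @rdname growth_equation
#' @param eq A `growth_equation`.
#' @param d2,d3 Intermediate and slow diffusion coefficients
#'   (1e-3 mm^2/s); vectorized.
#' @export
predict_growth <- function(eq, d2, d3) {
  stopifnot(inherits(eq, "growth_equation"))
  eq$intercept + eq$coef_d2 * d2 + eq$coef_d3 * d3
}

#' @export
print.growth_equation <- function(x, ...) {
  cat(sprintf(
    "Estimated growth rate = (%.4g) * D2 + (%.4g) * D3 + (%.4g)\n",
    x$coef_d2, x$coef_d3, x$intercept))
  cat("  (D2, D3 in 1e-3 mm^2/s; no-growth = 100)\n")
  invisible(x)
}
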