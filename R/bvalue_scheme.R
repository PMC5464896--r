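#' Diffusion-weighting scheme
#'
#' A b-value scheme records the diffusion weightings of a multi-b DWI
#' acquisition together with the number of signal averages (NSA) acquired at
#' each b-value. The default scheme is the 12-b-value protocol used
#' throughout this package: b = 0, 10, 20, 30, 50, 80, 100, 200, 400, 800,
#' 1000, 2000 s/mm^2 with 1 average for b <= 100, 2 for 200-800 and 3 for
#' b >= 1000.
#'
#' @param b_values Numeric vector of b-values in s/mm^2; must be strictly
#'   increasing and start at 0.
#' @param nsa Integer vector of signal averages per b-value (recycled if
#'   length 1); every entry must be >= 1.
#' @return An object of class `b_scheme`: a list with elements `b_values`
#'   and `nsa`.
#' @examples
#' sch <- default_b_scheme()
#' sch$b_values
#' @export
b_scheme <- function(b_values, nsa = 1L) {
  b_values <- as.numeric(b_values)
  if (length(b_values) < 2L) {
    stop("a b-value scheme needs at least two b-values", call. = FALSE)
  }
  if (b_values[1L] != 0) {
    stop("the first b-value must be 0 (it defines S0)", call. = FALSE)
  }
  if (any(diff(b_values) <= 0)) {
    stop("b-values must be strictly increasing", call. = FALSE)
  }
  nsa <- as.integer(rep_len(nsa, length(b_values)))
  if (any(nsa < 1L)) stop("nsa must be >= 1 for every b-value", call. = FALSE)
  structure(list(b_values = b_values, nsa = nsa), class = "b_scheme")
}

#' @rdname b_scheme
#' @export
default_b_scheme <- function() {
  b <- c(0, 10, 20, 30, 50, 80, 100, 200, 400, 800, 1000, 2000)
  nsa <- ifelse(b <= 100, 1L, ifelse(b <= 800, 2L, 3L))
  b_scheme(b, nsa)
}

#' ROI-mean signal curve
#'
#' Container for a region-of-interest (ROI) mean diffusion signal decay:
#' one mean intensity per b-value, with an optional background-noise
#' standard deviation used for SNR reporting. The signal at b = 0 defines
#' S0.
#'
#' @param scheme A [b_scheme()].
#' @param signal Numeric vector of mean ROI intensities (arbitrary units),
#'   one per b-value, all positive.
#' @param noise_sd Optional background noise SD (same units); either a
#'   scalar or one value per b-value.
#' @return An object of class `signal_curve`.
#' @examples
#' sc <- signal_curve(default_b_scheme(), exp(-default_b_scheme()$b_values / 1000))
#' s0(sc)
#' @export
signal_curve <- function(scheme, signal, noise_sd = NULL) {
  stopifnot(inherits(scheme, "b_scheme"))
  signal <- as.numeric(signal)
  if (length(signal) != length(scheme$b_values)) {
    stop("need exactly one signal per b-value", call. = FALSE)
  }
  if (any(!is.finite(signal)) || any(signal <= 0)) {
    stop("all signals must be finite and > 0", call. = FALSE)
  }
  if (!is.null(noise_sd)) {
    noise_sd <- as.numeric(rep_len(noise_sd, length(signal)))
    if (any(!is.finite(noise_sd)) || any(noise_sd <= 0)) {
      stop("noise_sd must be finite and > 0", call. = FALSE)
    }
  }
  structure(list(scheme = scheme, signal = signal, noise_sd = noise_sd),
            class = "signal_curve")
}

#' @rdname signal_curve
#' @param curve A `signal_curve`.
#' @export
s0 <- function(curve) {
  stopifnot(inherits(curve, "signal_curve"))
  curve$signal[[1L]]
}

#' Signal-to-noise ratio per b-value
#'
#' SNR is the ratio of the mean ROI signal intensity to the standard
#' deviation of the background noise, reported per b-value.
#'
#' @param curve A [signal_curve()] carrying `noise_sd`.
#' @return Named numeric vector of SNR values (names are the b-values), or
#'   `NA` per b-value (with a warning) when no noise SD is recorded.
#' @examples
#' sc <- signal_curve(b_scheme(c(0, 1000)), c(200, 100), noise_sd = 4)
#' compute_snr(sc)
#' @export
compute_snr <- function(curve) {
  stopifnot(inherits(curve, "signal_curve"))
  if (is.null(curve$noise_sd)) {
    warning("no noise SD recorded for this curve; SNR unavailable",
            call. = FALSE)
    return(stats::setNames(rep(NA_real_, length(curve$signal)),
                           curve$scheme$b_values))
  }
  stats::setNames(curve$signal / curve$noise_sd, curve$scheme$b_values)
}

#' @export
print.signal_curve <- function(x, ...) {
  cat("ROI-mean DWI signal curve:", length(x$signal), "b-values\n")
  df <- data.frame(b_value = x$scheme$b_values, nsa = x$scheme$nsa,
                   signal = x$signal)
  if (!is.null(x$noise_sd)) df$noise_sd <- x$noise_sd
  print(df, row.names = FALSE)
  invisible(x)
}
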