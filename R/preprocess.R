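# Offset-eliminating preprocessing operators.
#
# The strap-on pressure of a noseband sensor is an unknown constant that
# differs between animals and fittings; features computed on raw values
# confound behavior with fitting. Three operators remove it:
#   FOD  first-order difference           d[t] = x[t+1] - x[t]
#   LS   sliding-window least-squares slope (window 11, stride 1)
#   HPF  sixth-order high-pass Butterworth, 0.3 Hz cutoff at 50 Hz
# FOD and LS are exactly shift-invariant; HPF rejects DC up to a transient.

preprocessed_signal <- function(values, method, source_length) {
  structure(list(values = as.numeric(values), method = method,
                 source_length = as.integer(source_length)),
            class = "preprocessed_signal")
}

#' @export
print.preprocessed_signal <- function(x, ...) {
  cat(sprintf("<preprocessed_signal> %s: %d values (from %d samples)\n",
              x$method, length(x$values), x$source_length))
  invisible(x)
}

#' First-order difference
#'
#' Successive-sample differences: \code{d[t] = x[t+1] - x[t]}, shortening the
#' sequence by one. Eliminates any constant offset exactly; sensitive to
#' single-sample mechanical spikes (each spike produces two large opposite
#' excursions).
#'
#' @param x numeric vector (grams), length >= 2.
#' @return A \code{preprocessed_signal} of length \code{length(x) - 1}, in
#'   grams per sample step.
#' @export
first_order_difference <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L)
    stop("first_order_difference needs at least 2 samples", call. = FALSE)
  preprocessed_signal(diff(x), "FOD", length(x))
}

#' Sliding-window least-squares local slope
#'
#' For each window of \code{window} consecutive samples (advanced by
#' \code{stride}), the ordinary-least-squares slope of the samples against
#' the unit-spaced abscissa \code{1..window}:
#' \deqn{\hat s = \frac{N\sum_i c_i x_i - \sum_i c_i \sum_i x_i}
#'                     {N\sum_i c_i^2 - (\sum_i c_i)^2}}
#' with \eqn{c = (1, \dots, N)}. Slopes are in grams per sample step; each
#' slope is associated with its window's center sample. A constant offset
#' cancels exactly, and averaging over 11 points suppresses isolated spikes
#' far more than the first-order difference does.
#'
#' @param x numeric vector (grams), length >= \code{window}.
#' @param window sliding window length in samples (default 11).
#' @param stride window advance in samples (default 1).
#' @return A \code{preprocessed_signal} with
#'   \code{floor((length(x) - window) / stride) + 1} slopes.
#' @export
local_slope <- function(x, window = 11L, stride = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 2L || stride < 1L)
    stop("window must be >= 2 and stride >= 1", call. = FALSE)
  if (n < window)
    stop(sprintf("local_slope needs at least %d samples, got %d", window, n),
         call. = FALSE)
  cc <- seq_len(window)
  sum_c <- sum(cc)
  sum_c2 <- sum(cc^2)
  denom <- window * sum_c2 - sum_c^2
  # windowed sums via one-sided moving filters; entry j covers x[(j-w+1)..j]
  sx <- stats::filter(x, rep(1, window), sides = 1)
  sxc <- stats::filter(x, rev(cc), sides = 1)
  ends <- seq(window, n, by = stride)
  slopes <- (window * sxc[ends] - sum_c * sx[ends]) / denom
  preprocessed_signal(as.numeric(slopes), "LS", n)
}

# Second-order sections of an order-n high-pass digital Butterworth filter.
# Analog lowpass prototype poles -> highpass transform at the pre-warped
# cutoff -> bilinear transform -> conjugate pole pairs as biquads, each
# normalized to unit gain at Nyquist. Returns a list of (b, a) coefficient
# pairs. Direct transfer-function realization at order 6 with a 0.3 Hz
# cutoff is numerically unacceptable (poles cluster near z = 1); the cascade
# keeps each section well conditioned.
butter_highpass_sos <- function(order, cutoff_hz, sampling_rate) {
  if (order %% 2 != 0)
    stop("butter_highpass_sos supports even orders only", call. = FALSE)
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_rate / 2)
    stop("cutoff must lie in (0, sampling_rate/2)", call. = FALSE)
  fs2 <- 2 * sampling_rate
  wc <- fs2 * tan(pi * cutoff_hz / sampling_rate)  # pre-warped analog cutoff
  k <- seq_len(order / 2)
  theta <- pi * (2 * k + order - 1) / (2 * order)  # upper-half-plane poles
  p_lp <- complex(modulus = 1, argument = theta)
  p_hp <- wc / p_lp                                # LP -> HP: s -> wc/s
  z_p <- (fs2 + p_hp) / (fs2 - p_hp)               # bilinear
  lapply(seq_along(z_p), function(i) {
    a <- c(1, -2 * Re(z_p[i]), Mod(z_p[i])^2)
    gain <- (1 - a[2] + a[3]) / 4                  # unit gain at z = -1
    list(b = gain * c(1, -2, 1), a = a)
  })
}

#' High-pass Butterworth filter
#'
#' Removes frequency content below \code{cutoff_hz}, including the constant
#' strap-on pressure (DC gain is exactly zero). Realized as cascaded
#' second-order sections for numerical stability and applied causally
#' (forward pass) by default, matching streaming deployment on a wearable;
#' set \code{zero_phase = TRUE} for forward-backward filtering. Output
#' length equals input length. A step input decays through a documented
#' transient of 45 s at the default 0.3 Hz cutoff (a 1000 g step falls below
#' 1e-6 g by ~41 s, a 300 g step by ~35 s); offset invariance holds only
#' after that transient.
#'
#' @param x numeric vector (grams).
#' @param order filter order (even; default 6).
#' @param cutoff_hz cutoff frequency in Hz (default 0.3).
#' @param sampling_rate sampling frequency in Hz (default 50).
#' @param zero_phase if TRUE, apply forward and backward (zero phase lag).
#' @return A \code{preprocessed_signal} of the same length as \code{x}, in
#'   grams.
#' @export
highpass_butterworth <- function(x, order = 6L, cutoff_hz = 0.3,
                                 sampling_rate = 50, zero_phase = FALSE) {
  x <- as.numeric(x)
  if (length(x) < 3L * order)
    stop("input too short for stable filtering (need >= 3 * order samples)",
         call. = FALSE)
  sos <- butter_highpass_sos(order, cutoff_hz, sampling_rate)
  run <- function(v) {
    for (sec in sos)
      v <- as.numeric(signal::filter(sec$b, sec$a, v))
    v
  }
  y <- run(x)
  if (zero_phase) y <- rev(run(rev(y)))
  preprocessed_signal(y, "HPF", length(x))
}

#' Apply a preprocessing method by name
#'
#' Dispatcher used by the evaluation pipeline. \code{"none"} returns the
#' input unchanged (the control condition), \code{"fod"} and \code{"ls"}
#' operate on the given vector, and \code{"hpf"} filters it. Note that in
#' the evaluation pipeline HPF is applied to whole series before window
#' segmentation (see \code{\link{preprocess_series}}), while FOD and LS are
#' applied per window.
#'
#' @param x numeric vector.
#' @param method one of \code{"none"}, \code{"fod"}, \code{"ls"},
#'   \code{"hpf"}.
#' @param sampling_rate sampling rate, Hz (used by \code{"hpf"}).
#' @return A \code{preprocessed_signal}.
#' @export
preprocess <- function(x, method = c("none", "fod", "ls", "hpf"),
                       sampling_rate = 50) {
  method <- match.arg(tolower(method), c("none", "fod", "ls", "hpf"))
  switch(method,
         none = preprocessed_signal(as.numeric(x), "NONE", length(x)),
         fod = first_order_difference(x),
         ls = local_slope(x),
         hpf = highpass_butterworth(x, sampling_rate = sampling_rate))
}

#' High-pass filter a whole labeled series
#'
#' Applies \code{\link{highpass_butterworth}} to the full pressure trace of a
#' series, keeping timestamps and labels. The filter transient makes
#' per-window application wrong, so series-level filtering precedes window
#' segmentation in the HPF pipeline. Filtered values are near zero mean and
#' may be negative, so the result is returned as a plain list mirroring the
#' series structure (it is no longer constrained to the 0--2000 g sensor
#' range).
#'
#' @param series a \code{\link{pressure_series}}.
#' @param method \code{"hpf"} to filter, \code{"none"}/\code{"fod"}/\code{"ls"}
#'   to return the series unchanged (those operators run per window later).
#' @param ... passed to \code{\link{highpass_butterworth}}.
#' @return An object with the same fields as the input series.
#' @export
preprocess_series <- function(series, method = "hpf", ...) {
  stopifnot(inherits(series, "pressure_series"))
  method <- match.arg(tolower(method), c("none", "fod", "ls", "hpf"))
  if (method != "hpf") return(series)
  out <- unclass(series)
  out$pressure <- highpass_butterworth(series$pressure,
                                       sampling_rate = series$sampling_rate,
                                       ...)$values
  class(out) <- c("filtered_series", "pressure_series")
  out
}
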