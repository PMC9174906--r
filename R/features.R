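# Two feature schemes per window:
#   FDF  one-sided, unnormalized FFT magnitude spectrum (DC excluded)
#   TDSF 14 time-domain summary statistics
# FDF of an n-sample window has floor(n/2) bins at k * fs / n Hz; for the
# default 10 s window at 50 Hz (n = 500) that is 250 bins at 0.1 Hz spacing
# covering 0.1-25 Hz. Excluding the DC bin makes FDF exactly invariant to a
# constant pressure offset, which is why it tolerates residual offsets even
# without preprocessing.

feature_vector <- function(values, names, scheme) {
  v <- as.numeric(values)
  names(v) <- names
  structure(list(values = v, scheme = scheme), class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s: %d features\n", x$scheme,
              length(x$values)))
  utils::str(x$values, vec.len = 4)
  invisible(x)
}

#' Frequency-domain features (one-sided FFT magnitude spectrum)
#'
#' Magnitudes (complex modulus, no 1/n or 2/n scaling) of the discrete
#' Fourier transform at bins \code{k = 1 .. floor(n/2)}, i.e. frequencies
#' \code{k * sampling_rate / n}. The DC bin (k = 0) is excluded: it carries
#' the mean, hence the strap-on offset the pipeline is designed to ignore.
#' Feature names carry the bin frequencies.
#'
#' @param values numeric vector, length >= 2.
#' @param sampling_rate sampling frequency, Hz.
#' @return A \code{feature_vector} of length \code{floor(length(values)/2)},
#'   scheme \code{"FDF"}.
#' @export
fdf <- function(values, sampling_rate = 50) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2L)
    stop("fdf needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(x)))
    stop("fdf input must be finite", call. = FALSE)
  k <- seq_len(n %/% 2L)
  mag <- Mod(stats::fft(x))[k + 1L]
  freqs <- k * sampling_rate / n
  feature_vector(mag, sprintf("fdf_%.6gHz", freqs), "FDF")
}

# Biased moment-based skewness (m3 / m2^1.5) and Fisher excess kurtosis
# (m4 / m2^2 - 3); zero-variance inputs return 0 by convention. Delegated to
# e1071 type 1, which implements exactly these definitions.
safe_skewness <- function(x) {
  if (stats::var(x) == 0) return(0)
  e1071::skewness(x, type = 1)
}
safe_kurtosis <- function(x) {
  if (stats::var(x) == 0) return(0)
  e1071::kurtosis(x, type = 1)
}

#' Time-domain statistical features
#'
#' Fourteen summary statistics of a window, in fixed order: mean, variance,
#' SD, maximum, minimum, range, median, first quartile, third quartile,
#' interquartile range, root mean square, movement variation, skewness and
#' kurtosis. Variance and SD use the n-1 denominator; quartiles use linear
#' interpolation between order statistics (R quantile type 7); movement
#' variation is the mean absolute successive difference
#' \eqn{\frac{1}{n-1}\sum_t |x_{t+1}-x_t|}; skewness is the biased
#' moment-based estimate and kurtosis the Fisher (excess) form, both 0 by
#' convention on zero-variance input.
#'
#' @param values numeric vector, length >= 4 (kurtosis defined).
#' @return A \code{feature_vector} of length 14, scheme \code{"TDSF"}.
#' @export
tdsf <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 4L)
    stop("tdsf needs at least 4 samples", call. = FALSE)
  if (any(!is.finite(x)))
    stop("tdsf input must be finite", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  v <- c(
    mean = mean(x),
    variance = stats::var(x),
    sd = stats::sd(x),
    max = max(x),
    min = min(x),
    range = max(x) - min(x),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    iqr = q[3] - q[1],
    rms = sqrt(mean(x^2)),
    movement_variation = mean(abs(diff(x))),
    skewness = safe_skewness(x),
    kurtosis = safe_kurtosis(x)
  )
  feature_vector(v, names(v), "TDSF")
}

#' Feature matrix for a set of windows
#'
#' Runs the (preprocessing, scheme) pipeline over every window: FOD and LS
#' shorten each window before the transform (to 499 and 490 samples for the
#' 10 s default), \code{"none"} and \code{"hpf"} leave window length
#' unchanged (HPF must already have been applied at series level, see
#' \code{\link{preprocess_series}}). FDF is computed on the actual
#' preprocessed length, so feature count is consistent within a pipeline.
#'
#' @param windows list of \code{\link{window_sample}} objects.
#' @param preprocessing \code{"none"}, \code{"fod"}, \code{"ls"} or
#'   \code{"hpf"}.
#' @param scheme \code{"fdf"} or \code{"tdsf"}.
#' @return List with \code{x} (numeric matrix, rows = windows, named
#'   columns), \code{labels} (factor), \code{animal_id} (character),
#'   \code{preprocessing}, \code{scheme}.
#' @export
window_feature_matrix <- function(windows,
                                  preprocessing = c("none", "fod", "ls", "hpf"),
                                  scheme = c("fdf", "tdsf")) {
  preprocessing <- match.arg(tolower(preprocessing),
                             c("none", "fod", "ls", "hpf"))
  scheme <- match.arg(tolower(scheme), c("fdf", "tdsf"))
  if (length(windows) == 0L)
    stop("no windows to featurize", call. = FALSE)
  rows <- lapply(windows, function(w) {
    v <- w$values
    if (preprocessing == "fod") v <- first_order_difference(v)$values
    if (preprocessing == "ls") v <- local_slope(v)$values
    fv <- if (scheme == "fdf") fdf(v, w$sampling_rate) else tdsf(v)
    fv$values
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("windows produced inconsistent feature lengths; mixed window sizes?",
         call. = FALSE)
  x <- do.call(rbind, rows)
  rownames(x) <- NULL
  list(x = x,
       labels = factor(vapply(windows, function(w) as.character(w$label),
                              character(1)),
                       levels = behavior_labels()),
       animal_id = vapply(windows, function(w) w$animal_id, character(1)),
       preprocessing = toupper(preprocessing), scheme = toupper(scheme))
}

#' Export a feature matrix as CSV
#'
#' Rows are windows; columns are the named features plus \code{label} and
#' \code{animal_id}, for external inspection.
#'
#' @param fm result of \code{\link{window_feature_matrix}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  df <- as.data.frame(fm$x)
  df$label <- as.character(fm$labels)
  df$animal_id <- fm$animal_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
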