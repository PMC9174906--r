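# Independent oracles, deliberately naive: they share no code path with the
# implementation they check.

# O(n^2) discrete Fourier sum, one-sided magnitudes excluding DC.
dft_magnitude_oracle <- function(x) {
  n <- length(x)
  ks <- seq_len(n %/% 2)
  vapply(ks, function(k) {
    j <- 0:(n - 1)
    Mod(sum(x * exp(-2i * pi * k * j / n)))
  }, numeric(1))
}

# Per-window OLS slopes via lm(), the closed-form normal equations solved by
# an unrelated routine.
ls_oracle <- function(x, window = 11, stride = 1) {
  starts <- seq(1, length(x) - window + 1, by = stride)
  cc <- seq_len(window)
  vapply(starts, function(s) {
    unname(stats::coef(stats::lm(x[s:(s + window - 1)] ~ cc))[2])
  }, numeric(1))
}

# Formula-by-formula recomputation of the 14 time-domain statistics using
# explicit sums and hand-coded interpolated quantiles.
tdsf_oracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  s <- sort(x)
  qint <- function(p) { # linear interpolation between order statistics
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  c(mean = mu,
    variance = sum((x - mu)^2) / (n - 1),
    sd = sqrt(sum((x - mu)^2) / (n - 1)),
    max = s[n], min = s[1], range = s[n] - s[1],
    median = qint(0.5), q1 = qint(0.25), q3 = qint(0.75),
    iqr = qint(0.75) - qint(0.25),
    rms = sqrt(sum(x^2) / n),
    movement_variation = sum(abs(x[-1] - x[-n])) / (n - 1),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}
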