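test_that("a 10 s window at 50 Hz yields 250 spectrum features on a 0.1-25 Hz grid", {
  f <- fdf(rnorm(500), 50)
  expect_length(f$values, 250)
  freqs <- as.numeric(sub("Hz$", "", sub("^fdf_", "", names(f$values))))
  expect_equal(freqs, seq(0.1, 25, by = 0.1), tolerance = 1e-9)
})

test_that("pure tones land in their own bin and zero input gives zero features", {
  t <- (0:499) / 50
  f <- fdf(sin(2 * pi * 1.0 * t), 50)
  expect_equal(unname(which.max(f$values)), 10L)  # 1.0 Hz = bin 10 at 0.1 Hz spacing
  expect_equal(unname(f$values[10]), 250, tolerance = 1e-6) # n/2 for unit tone
  expect_true(all(fdf(rep(0, 100), 50)$values == 0))
  expect_error(fdf(3), "at least 2")
})

test_that("spectrum magnitudes match a direct discrete Fourier sum", {
  t <- (0:499) / 50
  x <- sin(2 * pi * 0.7 * t) + 0.5 * sin(2 * pi * 1.3 * t)
  got <- unname(fdf(x, 50)$values)
  want <- dft_magnitude_oracle(x)
  expect_equal(got, want, tolerance = 1e-6)
  top2 <- order(got, decreasing = TRUE)[1:2]
  expect_setequal(top2, c(7L, 13L))  # 0.7 and 1.3 Hz bins
  set.seed(41)
  for (n in c(64, 127, 350)) {
    x <- rnorm(n, 100, 20)
    expect_equal(unname(fdf(x, 50)$values), dft_magnitude_oracle(x),
                 tolerance = 1e-6)
  }
})

test_that("excluding the DC bin makes the spectrum exactly offset-invariant", {
  set.seed(8)
  x <- rnorm(500, 300, 50)
  expect_equal(unname(fdf(x + 123.456, 50)$values), unname(fdf(x, 50)$values),
               tolerance = 1e-9)
})

test_that("one-sided magnitudes satisfy a Parseval identity with DC restored", {
  set.seed(15)
  for (n in c(64, 101, 500)) {
    x <- rnorm(n)
    mags <- unname(fdf(x, 50)$values)
    dc <- abs(sum(x))
    # full two-sided energy: DC + mirrored interior bins (+ unmirrored
    # Nyquist when n is even)
    k <- seq_along(mags)
    mult <- ifelse(n %% 2 == 0 & k == n / 2, 1, 2)
    expect_equal(dc^2 + sum(mult * mags^2), n * sum(x^2), tolerance = 1e-6)
  }
})

test_that("the 14 time-domain statistics match hand arithmetic and an independent recomputation", {
  f <- tdsf(c(1, 2, 3, 4))$values
  expect_equal(unname(f[c("mean", "max", "min", "range", "median")]),
               c(2.5, 4, 1, 3, 2.5))
  g <- tdsf(rep(5, 10))$values
  expect_equal(unname(g[c("variance", "sd", "range", "iqr", "rms",
                          "movement_variation", "skewness", "kurtosis")]),
               c(0, 0, 0, 0, 5, 0, 0, 0))
  set.seed(77)
  x <- rnorm(100, 50, 12)
  expect_equal(tdsf(x)$values, tdsf_oracle(x), tolerance = 1e-9)
  expect_error(tdsf(c(1, 2, 3)), "at least 4")
})

test_that("time-domain order statistics are internally consistent", {
  set.seed(19)
  for (rep in 1:10) {
    v <- tdsf(runif(60, 0, 600))$values
    expect_true(v["min"] <= v["q1"] && v["q1"] <= v["median"] &&
                  v["median"] <= v["q3"] && v["q3"] <= v["max"])
    expect_equal(unname(v["range"]), unname(v["max"] - v["min"]))
    expect_equal(unname(v["iqr"]), unname(v["q3"] - v["q1"]))
    expect_equal(unname(v["variance"]), unname(v["sd"])^2, tolerance = 1e-12)
  }
})

test_that("the feature matrix reflects the preprocessing length contracts", {
  herd <- test_herd(2, 30, seed = 3)
  w <- segment_windows_multi(herd, 10)
  expect_equal(ncol(window_feature_matrix(w, "none", "fdf")$x), 250)
  expect_equal(ncol(window_feature_matrix(w, "fod", "fdf")$x), 249)
  expect_equal(ncol(window_feature_matrix(w, "ls", "fdf")$x), 245)
  fm <- window_feature_matrix(w, "ls", "tdsf")
  expect_equal(ncol(fm$x), 14)
  expect_equal(nrow(fm$x), length(w))
  expect_equal(as.character(fm$labels),
               unname(vapply(w, function(x) as.character(x$label), character(1))))
  expect_true(all(is.finite(fm$x)))
})

test_that("feature matrices export to CSV with label and animal columns", {
  herd <- test_herd(1, 30, seed = 3)
  fm <- window_feature_matrix(segment_windows_multi(herd, 10), "ls", "tdsf")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  df <- read.csv(path)
  expect_equal(nrow(df), nrow(fm$x))
  expect_true(all(c("label", "animal_id") %in% names(df)))
})
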