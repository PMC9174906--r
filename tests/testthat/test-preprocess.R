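test_that("first-order difference matches its definition and length contract", {
  expect_equal(first_order_difference(c(1, 3, 6))$values, c(2, 3))
  expect_equal(first_order_difference(rep(7, 50))$values, rep(0, 49))
  x <- cumsum(rnorm(100))
  d <- first_order_difference(x)
  expect_length(d$values, 99)
  expect_equal(d$source_length, 100L)
  expect_error(first_order_difference(5), "at least 2")
})

test_that("local slope is exact on ramps, zero on constants, and obeys the length contract", {
  ramp <- 5 + 2 * (0:29)
  ls <- local_slope(ramp)
  expect_equal(ls$values, rep(2, 20))   # 30 samples, window 11 -> 20 slopes
  expect_length(local_slope(rnorm(30))$values, 20)
  expect_equal(local_slope(rep(3.3, 40))$values, rep(0, 30))
  expect_error(local_slope(rnorm(10)), "at least 11")
  # stride and window are honored
  expect_length(local_slope(rnorm(100), window = 21, stride = 4)$values,
                (100 - 21) %/% 4 + 1)
})

test_that("local slope equals independently fitted OLS on every window", {
  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(60, 200, 40)
    got <- local_slope(x)$values
    want <- ls_oracle(x)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # non-default window
  x <- runif(50, 0, 500)
  expect_equal(local_slope(x, window = 7)$values, ls_oracle(x, window = 7),
               tolerance = 1e-9)
})

test_that("offset elimination: FOD and LS are bit-identical under constant shifts", {
  set.seed(12)
  for (rep in 1:5) {
    x <- round(runif(200, 0, 500))           # integer grams: shift is exact
    c0 <- round(runif(1, 0, 1000))
    expect_identical(first_order_difference(x + c0)$values,
                     first_order_difference(x)$values)
    expect_identical(local_slope(x + c0)$values, local_slope(x)$values)
  }
})

test_that("the high-pass filter rejects DC, passes the chewing band, and preserves length", {
  # constant input decays below 1e-6 g after the documented 45 s transient
  y <- highpass_butterworth(rep(300, 60 * 50))$values
  expect_length(y, 3000)
  expect_lt(max(abs(y[(45 * 50):3000])), 1e-6)
  # 5 Hz sinusoid is passed within 1% post-transient
  t <- (0:2999) / 50
  ys <- highpass_butterworth(sin(2 * pi * 5 * t))$values
  expect_equal(max(abs(ys[2500:3000])), 1, tolerance = 0.01)
  # offset invariance within tolerance after the transient
  x <- rnorm(3000, 250, 30)
  d <- highpass_butterworth(x + 400)$values - highpass_butterworth(x)$values
  expect_lt(max(abs(d[(45 * 50):3000])), 1e-6)
  expect_error(highpass_butterworth(rnorm(100), cutoff_hz = 30),
               "cutoff")
  expect_error(highpass_butterworth(rnorm(5)), "too short")
})

test_that("zero-phase filtering removes the phase lag of the causal pass", {
  t <- (0:4999) / 50
  x <- sin(2 * pi * 2 * t)
  yz <- highpass_butterworth(x, zero_phase = TRUE)$values
  mid <- 2000:3000
  expect_equal(yz[mid], x[mid], tolerance = 0.01)
})

test_that("all three operators leave long stationary signals with near-zero mean", {
  cfg <- simulation_config(behavior_bouts = data.frame(label = "RUMINATION",
                                                       duration = 180),
                           seed = 17)
  s <- simulate_series(cfg)
  expect_lt(abs(mean(first_order_difference(s$pressure)$values)), 0.1)
  expect_lt(abs(mean(local_slope(s$pressure)$values)), 0.1)
  hp <- highpass_butterworth(s$pressure)$values
  expect_lt(abs(mean(hp[(45 * 50):length(hp)])), 0.5)
})

test_that("LS suppresses mechanical spikes more than FOD does", {
  cfg <- simulation_config(
    behavior_bouts = data.frame(label = "RUMINATION", duration = 120),
    spike_rate = 6, seed = 23)
  s <- simulate_series(cfg)
  fodv <- first_order_difference(s$pressure)$values
  lsv <- local_slope(s$pressure)$values
  expect_lt(max(abs(lsv)), max(abs(fodv)))
})

test_that("the preprocess dispatcher applies the named operator with its length contract", {
  x <- rnorm(500, 200, 30)
  expect_identical(preprocess(x, "none")$values, x)
  expect_length(preprocess(x, "fod")$values, 499)
  expect_length(preprocess(x, "ls")$values, 490)
  expect_length(preprocess(x, "hpf")$values, 500)
  expect_equal(preprocess(x, "ls")$method, "LS")
})
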