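test_that("zero-phase band-pass keeps the passband and rejects the stopband", {
  fs <- 1000
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x5 <- sin(2 * pi * 5 * t)
  y5 <- zero_phase_bandpass(x5, fs, c(4, 6))
  core <- 10000:50000
  expect_lt(abs(max(y5[core]) - 1), 0.02) # passband amplitude within 2%
  # zero net phase: peak cross-correlation at lag 0
  cc <- stats::ccf(y5[core], x5[core], lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  y50 <- zero_phase_bandpass(sin(2 * pi * 50 * t), fs, c(4, 6))
  expect_lt(sd(y50) / sd(sin(2 * pi * 50 * t)), 0.01)
})

test_that("band-pass agrees with a frequency-domain masking oracle", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t) + sin(2 * pi * 5 * t)
  y <- zero_phase_bandpass(x, fs, c(4, 6))
  oracle <- fft_mask_bandpass(x, fs, c(4, 6))
  core <- 5000:25000
  expect_gt(cor(y[core], oracle[core]), 0.99)
  expect_gt(cor(y[core], sin(2 * pi * 5 * t)[core]), 0.99)
})

test_that("band and input validation reject impossible requests", {
  expect_error(zero_phase_bandpass(rnorm(1000), 100, c(4, 60)), "invalid band")
  expect_error(zero_phase_bandpass(c(rnorm(999), NA), 100, c(4, 6)),
    "non-finite")
  expect_error(zero_phase_bandpass(rnorm(10000), 10000, c(4, 6), order = 500),
    "degenerate")
})

test_that("decimation preserves the passband and removes aliases", {
  fs <- 10000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  y5 <- decimate_to(sin(2 * pi * 5 * t), fs, 1000)
  expect_lt(abs(max(abs(y5[2000:8000])) - 1), 0.01)
  y600 <- decimate_to(sin(2 * pi * 600 * t), fs, 1000)
  expect_lt(sd(y600) / sd(sin(2 * pi * 600 * t)), 0.05)

  # broadband noise: output variance matches the sub-500 Hz spectral mass
  set.seed(2)
  w <- rnorm(length(t))
  yd <- decimate_to(w, fs, 1000)
  pw <- Mod(fft(w))^2 / length(w)^2
  f <- (seq_along(w) - 1) * fs / length(w)
  v500 <- 2 * sum(pw[f > 0 & f < 500])
  expect_lt(abs(var(yd) / v500 - 1), 0.10)

  expect_error(decimate_to(rnorm(100), 500, 1000), "cannot upsample")
})

test_that("the PSC band-pass realizes its design template", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  att_db <- function(f) {
    y <- psc_bandpass(sin(2 * pi * f * t), fs)
    -20 * log10(max(abs(y[2000:8000])))
  }
  expect_lte(att_db(80), 1) # passband
  expect_gte(att_db(2), 60) # low stopband
  expect_gte(att_db(300), 40) # high stopband
  expect_error(psc_bandpass(rnorm(5000), 5000), "decimate first")
})

test_that("the power envelope hugs a constant-amplitude oscillation", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  env <- power_envelope(sin(2 * pi * 5 * t), 200)
  core <- env[2000:18000]
  expect_lt(max(abs(core - 0.5)) / 0.5, 0.15) # near mean power of 1/2
})
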