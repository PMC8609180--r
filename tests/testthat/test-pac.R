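test_that("the modulation index hits its analytic extremes", {
  set.seed(1)
  ph <- runif(20000, -pi, pi)
  expect_equal(modulation_index(ph, rep(2.5, 20000))$mi, 0)

  # all amplitude mass in one bin: MI -> 1
  amp <- ifelse(ph >= 0 & ph < (2 * pi / 18) - pi + pi, 1, 0)
  amp <- ifelse(ph >= -pi & ph < -pi + 2 * pi / 18, 1, 1e-300)
  expect_gt(modulation_index(ph, amp)$mi, 0.999)

  expect_error(modulation_index(ph[1:10], rep(1, 10)),
    "insufficient phase coverage")
  expect_error(modulation_index(ph, rep(-1, 20000)), "domain error")
  expect_error(modulation_index(ph, rep(1, 5)), "equal length")
})

test_that("the modulation index equals a brute-force KL oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(500:3000, 1)
    ph <- runif(n, -pi, pi)
    am <- exp(rnorm(n, 0, sample(c(0.1, 1, 3), 1)))
    expect_lt(abs(modulation_index(ph, am)$mi - mi_bruteforce(ph, am)), 1e-12)
  }
  # the spec's cosine-modulated case
  ph <- seq(-pi, pi - 1e-6, length.out = 36000)
  am <- 1 + 0.5 * cos(ph)
  expect_lt(abs(modulation_index(ph, am)$mi - mi_bruteforce(ph, am)), 1e-12)
})

test_that("MI is invariant to amplitude scaling and phase rotation", {
  set.seed(8)
  ph <- runif(30000, -pi, pi)
  am <- 1 + 0.6 * cos(ph) + 0.05 * rnorm(30000)
  am <- pmax(am, 0)
  m0 <- modulation_index(ph, am)$mi
  expect_equal(modulation_index(ph, 137 * am)$mi, m0, tolerance = 1e-12)
  # rotating all phases by a whole bin relabels bins only
  shift <- 2 * pi / 18
  expect_lt(abs(modulation_index(ph + shift, am)$mi - m0), 1e-9)
  expect_true(m0 >= 0 && m0 <= 1)
})

test_that("Morlet maps localize tones, reject DC, and track a chirp", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  tf <- morlet_tf(sin(2 * pi * 5 * t), fs, 1:12)
  pow <- rowMeans(Mod(tf$coeffs)^2)
  expect_equal(tf$freqs_Hz[which.max(pow)], 5)

  # away from edge transients, a zero-mean wavelet ignores DC entirely
  tf_dc <- morlet_tf(rep(3, length(t)), fs, 1:12)
  tf_1hz <- morlet_tf(sin(2 * pi * t), fs, 1:12)
  mid <- seq(round(0.35 * length(t)), round(0.65 * length(t)))
  expect_lt(max(rowMeans(Mod(tf_dc$coeffs[, mid])^2)),
    0.01 * max(rowMeans(Mod(tf_1hz$coeffs[, mid])^2)))

  ch <- sin(2 * pi * (2 * t + (8 / 40) * t^2)) # 2 -> 10 Hz linear chirp
  tfc <- morlet_tf(ch, fs, seq(1, 12, by = 0.25))
  ridge <- tfc$freqs_Hz[apply(Mod(tfc$coeffs), 2, which.max)]
  f_inst <- 2 + (8 / 20) * t
  central <- t >= 2 & t <= 18
  expect_lt(max(abs(ridge[central] - f_inst[central])), 1)

  expect_error(morlet_tf(rnorm(100), 100, c(10, 60)), "invalid frequency")
})

test_that("baseline z-scoring is centered, monotone, and guards degeneracy", {
  set.seed(5)
  zmeans <- vapply(1:20, function(s) {
    set.seed(s)
    tf <- morlet_tf(rnorm(20000), 1000, seq(2, 12, by = 2))
    z <- zscore_to_baseline(tf, c(0, 10))
    mean(z$z[, tf$times_s >= 10])
  }, numeric(1))
  expect_lt(abs(mean(zmeans)), 0.2)

  # identical baseline and evaluation window: mean z exactly 0
  tf <- morlet_tf(rnorm(4000), 1000, c(5, 10))
  z <- zscore_to_baseline(tf, c(0, 4))
  expect_equal(mean(z$z), 0, tolerance = 1e-12)

  # power increase after baseline gives positive z at that frequency
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 6 * t) * ifelse(t > 10, 2, 1) + 0.1 * rnorm(length(t))
  tf2 <- morlet_tf(x, fs, c(3, 6, 9))
  z2 <- zscore_to_baseline(tf2, c(1, 9))
  expect_gt(mean(z2$z[2, z2$times_s > 11 & z2$times_s < 19]), 1)

  tf3 <- morlet_tf(rep(0, 3000), 1000, c(5, 10))
  expect_warning(zscore_to_baseline(tf3, c(0, 2)), "zero baseline variance")
})

test_that("the comodulogram recovers an injected coupling pair", {
  sim <- quick_coupled_fixture(seed = 2)
  pac <- comodulogram(sim$recording, center_s = 12.5)
  expect_lte(abs(pac$peak_pair[["phase_Hz"]] - 5), 1)
  expect_lte(abs(pac$peak_pair[["amp_Hz"]] - 80), 10)
  expect_true(all(pac$mi >= 0 & pac$mi <= 1))

  # swapping phase/amplitude roles collapses the coupling
  rev <- comodulogram(sim$recording, center_s = 12.5,
    phase_freqs = c(75, 80, 85), amp_freqs = c(4, 5, 6))
  expect_gt(pac$mi["5", "80"], 10 * rev$mi["80", "5"])

  expect_error(comodulogram(sim$recording, center_s = 1), "window out of range")
})

test_that("an identity permutation reproduces the observed MI exactly", {
  sim <- quick_coupled_fixture(seed = 3)
  pac <- comodulogram(sim$recording, center_s = 12.5)
  block_len <- max(1L, round(0.01 * pac$fs))
  n_blocks <- ceiling(ncol(pac$bins) / block_len)
  mi_id <- slicephys:::apply_phase_permutation(pac, seq_len(n_blocks))
  expect_equal(mi_id, unname(pac$mi), tolerance = 1e-14)
})

test_that("surrogates certify true coupling and bound the null", {
  sim <- quick_coupled_fixture(seed = 2)
  pac <- comodulogram(sim$recording, center_s = 12.5)
  pac <- surrogate_significance(pac, n_surrogates = 60, seed = 1)
  expect_gt(pac$z[which.max(pac$mi)], 3)
  expect_true(pac$sig_mask[which.max(pac$mi)])
  # surrogate mean MI does not exceed the observed MI at the peak
  expect_lt(pac$surrogate_mean[which.max(pac$mi)], max(pac$mi))
})

test_that("edge padding keeps the MI stable against a longer extraction", {
  sim <- gen_coupled_lfp(coupled_lfp_spec(duration_s = 40, burst_times_s = 10,
    burst_dur_s = 20, seed = 9))
  pac_pad <- comodulogram(sim$recording, center_s = 20, window_s = 10,
    pad_s = 5, phase_freqs = c(4, 5, 6), amp_freqs = seq(70, 90, 5))
  pac_long <- comodulogram(sim$recording, center_s = 20, window_s = 10,
    pad_s = 8, phase_freqs = c(4, 5, 6), amp_freqs = seq(70, 90, 5))
  expect_lt(max(abs(pac_pad$mi - pac_long$mi) / pmax(pac_long$mi, 1e-6)), 0.05)
})

test_that("the power vs MI control labels coupling plausibility", {
  r <- mi_power_control(c(1, 2, 3), c(0.3, 0.2, 0.1))
  expect_equal(r$rho, -1)
  expect_equal(r$verdict, "consistent with true PAC")
  expect_equal(r$slope_sign, -1)

  expect_error(mi_power_control(c(1, 2, 3), c(0.2, 0.2, 0.2)),
    "undefined correlation")

  set.seed(10)
  r2 <- mi_power_control(rnorm(100), rnorm(100))
  expect_lt(abs(r2$rho), 0.3)
})
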