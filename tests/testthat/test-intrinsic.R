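test_that("spike detection counts inserted and periodic spikes", {
  fs <- 10000
  # subthreshold depolarization only
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  sub <- -70 + 10 * (1 - exp(-t / 0.02))
  expect_length(detect_spikes(sub, fs), 0L)

  # 100 Hz periodic train for 0.5 s -> 50 spikes
  defl <- slicephys:::ap_deflection(fs)
  vm <- rep(-60, fs)
  for (ts in seq(0.1, 0.595, by = 0.01)) {
    i0 <- round(ts * fs) + 1L
    idx <- i0:min(length(vm), i0 + length(defl) - 1L)
    vm[idx] <- vm[idx] + defl[seq_along(idx)]
  }
  expect_length(detect_spikes(vm, fs), 50L)

  # 3 inserted templates at known times, located within 0.2 ms
  vm3 <- rep(-65, fs)
  times <- c(0.21, 0.52, 0.80)
  for (ts in times) {
    i0 <- round(ts * fs) + 1L
    idx <- i0:(i0 + length(defl) - 1L)
    vm3[idx] <- vm3[idx] + defl[seq_along(idx)]
  }
  got <- detect_spikes(vm3, fs)
  peak_off <- (which.max(defl) - 1) / fs
  expect_length(got, 3L)
  expect_true(all(abs(got - (times + peak_off)) < 2e-4))
})

test_that("AP features match the template's analytic landmarks", {
  tpl <- ap_template()
  f <- ap_features(tpl$vm, tpl$fs, tpl$spike_time_s)
  expect_equal(f$threshold_mV, tpl$truth$threshold_mV, tolerance = 0.02)
  expect_equal(f$amplitude_mV, tpl$truth$amplitude_mV, tolerance = 0.02)
  expect_lt(abs(f$half_width_ms - tpl$truth$half_width_ms),
    2 * 1000 / tpl$fs) # within a sample of the closed form
  expect_equal(f$ahp_mV, tpl$truth$ahp_mV, tolerance = 0.05)
  expect_false(f$flagged)
})

test_that("a symmetric triangular spike has half-width half its base", {
  fs <- 50000
  w_ms <- 2 # full base width
  half_n <- round(w_ms / 2 / 1000 * fs)
  tri <- c(rep(-70, 1000), -70 + 80 * seq_len(half_n) / half_n,
    -70 + 80 * rev(seq_len(half_n) - 1) / half_n, rep(-70, 2000))
  pk <- (1000 + half_n) / fs
  f <- ap_features(tri, fs, pk, dvdt_thresh_mV_per_ms = 20)
  expect_equal(f$half_width_ms, w_ms / 2, tolerance = 0.05)
})

test_that("AP features survive noise across seeds", {
  tpl <- ap_template()
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    vm <- tpl$vm + rnorm(length(tpl$vm), 0, 0.5)
    f <- ap_features(vm, tpl$fs, tpl$spike_time_s)
    all(
      abs(f$threshold_mV - tpl$truth$threshold_mV) / abs(tpl$truth$threshold_mV) < 0.05,
      abs(f$amplitude_mV - tpl$truth$amplitude_mV) / tpl$truth$amplitude_mV < 0.05,
      abs(f$half_width_ms - tpl$truth$half_width_ms) / tpl$truth$half_width_ms < 0.05,
      abs(f$ahp_mV - tpl$truth$ahp_mV) / tpl$truth$ahp_mV < 0.05
    )
  }, logical(1))
  expect_true(all(ok))
})

test_that("voltage offsets shift only rmp and threshold", {
  tpl <- ap_template()
  f0 <- ap_features(tpl$vm, tpl$fs, tpl$spike_time_s)
  f1 <- ap_features(tpl$vm + 12.5, tpl$fs, tpl$spike_time_s)
  expect_equal(f1$threshold_mV, f0$threshold_mV + 12.5, tolerance = 1e-9)
  expect_equal(f1$amplitude_mV, f0$amplitude_mV, tolerance = 1e-9)
  expect_equal(f1$half_width_ms, f0$half_width_ms, tolerance = 1e-9)
  expect_equal(f1$ahp_mV, f0$ahp_mV, tolerance = 1e-9)
})

test_that("passive properties are exact on noiseless RC data", {
  spec <- step_protocol_spec(sag_amp_mV = 0, rebound_amp_mV = 0,
    noise_sd_mV = 0)
  prot <- gen_step_protocol(spec)
  pp <- passive_props(prot$steps)
  expect_equal(pp$rmp_mV, spec$rmp_mV, tolerance = 1e-6)
  expect_lt(abs(pp$r_in_MOhm - spec$r_in_MOhm) / spec$r_in_MOhm, 0.02)
  expect_lt(abs(pp$tau_ms - spec$tau_ms) / spec$tau_ms, 0.05)
})

test_that("R and tau are recovered across a parameter sweep", {
  set.seed(40)
  for (i in 1:6) {
    r <- runif(1, 50, 300)
    tau <- runif(1, 5, 50)
    spec <- step_protocol_spec(r_in_MOhm = r, tau_ms = tau, sag_amp_mV = 0,
      rebound_amp_mV = 0, noise_sd_mV = 0, fi_gain_Hz_per_pA = 0,
      step_amps_pA = c(-100, -50, 50))
    pp <- passive_props(gen_step_protocol(spec)$steps)
    expect_lt(abs(pp$r_in_MOhm - r) / r, 0.02)
    expect_lt(abs(pp$tau_ms - tau) / tau, 0.05)
  }
})

test_that("sag and rebound vanish on pure RC responses", {
  set.seed(41)
  for (i in 1:6) {
    spec <- step_protocol_spec(
      r_in_MOhm = runif(1, 80, 250), tau_ms = runif(1, 8, 40),
      sag_amp_mV = 0, rebound_amp_mV = 0, noise_sd_mV = 0,
      step_amps_pA = c(-200, -50)
    )
    sr <- sag_rebound(gen_step_protocol(spec)$steps[[1]])
    expect_lt(abs(sr$sag_mV), 0.01)
    expect_lt(abs(sr$rebound_mV), 0.01)
  }
})

test_that("programmed sag and rebound amplitudes are recovered", {
  prot <- gen_step_protocol(step_protocol_spec(noise_sd_mV = 0))
  sr <- sag_rebound(prot$steps[[1]])
  expect_lt(abs(sr$sag_mV - 2.57), 0.2)
  expect_lt(abs(sr$rebound_mV - 1.86), 0.2)
})

test_that("F-I analysis shifts to one step below rheobase", {
  # counting contract on constructed counts
  prot <- gen_step_protocol(step_protocol_spec(noise_sd_mV = 0))
  fi <- fi_analysis(prot$steps)
  expect_equal(fi$rheobase_pA, 100)
  expect_equal(fi$shift_origin_pA, 50)
  expect_equal(fi$fi$n_spikes[fi$fi$current_pA < 100],
    rep(0, sum(fi$fi$current_pA < 100)))
  expect_lt(abs(fi$slope_Hz_per_pA - 0.204) / 0.204, 0.10)

  # exact line: rates 0,4,8,12 at shifted 0,50,100,150 -> slope 0.08
  rates <- c(0, 4, 8, 12)
  sh <- c(0, 50, 100, 150)
  expect_equal(unname(coef(lm(rates ~ sh))[2]), 0.08)

  # no spikes anywhere -> flagged
  prot0 <- gen_step_protocol(step_protocol_spec(fi_gain_Hz_per_pA = 0,
    step_amps_pA = c(-100, -50, 50)))
  fi0 <- fi_analysis(prot0$steps)
  expect_true(fi0$flagged)
  expect_true(is.na(fi0$rheobase_pA))
})

test_that("membrane_props assembles the full per-cell summary", {
  prot <- gen_step_protocol(step_protocol_spec(noise_sd_mV = 0))
  mp <- membrane_props(prot$steps)
  s <- mp$summary
  expect_equal(s$rmp_mV, -73.62, tolerance = 0.01)
  expect_equal(s$sag_mV, 2.57, tolerance = 0.2)
  expect_equal(s$rheobase_pA, 100)
  expect_true(is.finite(s$half_width_ms))
  expect_equal(nrow(tidy(mp)), ncol(s))
})
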