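test_that("generators are deterministic under a fixed seed", {
  a <- gen_coupled_lfp(coupled_lfp_spec(duration_s = 10, burst_times_s = 4,
    burst_dur_s = 1, seed = 3))
  b <- gen_coupled_lfp(coupled_lfp_spec(duration_s = 10, burst_times_s = 4,
    burst_dur_s = 1, seed = 3))
  expect_identical(a$recording$data, b$recording$data)

  p1 <- gen_psc_trace(psc_trace_spec(duration_s = 5, seed = 4))
  p2 <- gen_psc_trace(psc_trace_spec(duration_s = 5, seed = 4))
  expect_identical(p1$recording$data, p2$recording$data)
  expect_identical(p1$truth$events, p2$truth$events)
})

test_that("coupled-LFP spec validation catches impossible burst layouts", {
  expect_error(coupled_lfp_spec(burst_times_s = c(1, 1.3), burst_dur_s = 0.7),
    "bursts overlap")
  expect_error(coupled_lfp_spec(burst_times_s = 59.9, burst_dur_s = 0.7,
    duration_s = 60), "within the recording")
  expect_error(coupled_lfp_spec(coupling_depth = 1.4), "coupling_depth")
  expect_error(coupled_lfp_spec(carrier_band_Hz = c(4, 80),
    coupled_amp_band_Hz = c(75, 85)), "below")
})

test_that("lagged pairs realize the requested delay", {
  spec <- coupled_lfp_spec(duration_s = 10, burst_times_s = 4, burst_dur_s = 1,
    fs_Hz = 1000, noise_sd = 0, seed = 1)
  sim <- gen_lagged_pair(spec, lag_ms = 20)
  expect_identical(sim$truth$lag_ms, 20) # integer samples at 1 kHz
  d <- 20 # samples
  n <- n_samples(sim$recording)
  expect_equal(sim$recording$data[2, (d + 1):n],
    sim$recording$data[1, 1:(n - d)])

  sim0 <- gen_lagged_pair(spec, lag_ms = 0)
  expect_identical(sim0$recording$data[1, ], sim0$recording$data[2, ])
})

test_that("PSC traces are additive in their kernels and linear in amplitude", {
  spec <- psc_trace_spec(duration_s = 5, rate_Hz = 0.6, noise_sd_pA = 0,
    seed = 6)
  sim <- gen_psc_trace(spec)
  n_ev <- nrow(sim$truth$events)
  expect_gt(n_ev, 0)
  # trace equals the sum of the individual kernels exactly
  fs <- sim$recording$fs
  kern <- slicephys:::biexp_kernel(fs, spec$rise_ms, spec$decay_ms)
  manual <- numeric(n_samples(sim$recording))
  for (i in seq_len(n_ev)) {
    i0 <- round(sim$truth$events$time_s[i] * fs) + 1L
    idx <- i0:min(length(manual), i0 + length(kern) - 1L)
    manual[idx] <- manual[idx] - sim$truth$events$amp_pA[i] * kern[seq_along(idx)]
  }
  expect_equal(get_channel(sim$recording), manual, tolerance = 1e-12)

  # doubling the mean amplitude doubles the event component exactly
  spec2 <- psc_trace_spec(duration_s = 5, rate_Hz = 0.6, noise_sd_pA = 0,
    amp_mean_pA = 2 * spec$amp_mean_pA, seed = 6)
  sim2 <- gen_psc_trace(spec2)
  expect_equal(sim2$recording$data, 2 * sim$recording$data, tolerance = 1e-12)

  # inward polarity means negative-going peaks
  expect_true(all(apply(sim$recording$data, 1, min) <= 0))
  expect_lt(min(sim$recording$data), -1)
})

test_that("Poisson event counts match their rate over many seeds", {
  counts <- vapply(1:50, function(s) {
    spec <- psc_trace_spec(duration_s = 100, rate_Hz = 10, seed = s)
    withr::with_seed(spec$seed, rpois(1, spec$rate_Hz * spec$duration_s))
  }, numeric(1))
  expect_gte(mean(counts), 900)
  expect_lte(mean(counts), 1100)
})

test_that("IV series cross zero at the programmed reversal potential", {
  iv <- gen_iv_series(2, -36, seq(-70, 20, by = 10), noise_sd = 0, seed = 1)
  fit <- lm(auc ~ hold_mV, data = iv$points)
  expect_equal(-coef(fit)[[1]] / coef(fit)[[2]], -36, tolerance = 1e-9)
  iv0 <- gen_iv_series(0, -36, c(-70, 0, 20), noise_sd = 0, seed = 1)
  expect_true(all(iv0$points$auc == 0))
  expect_error(gen_iv_series(1, -36, holds_mV = -70), "underdetermined")
})

test_that("step responses obey Ohm's law and the programmed kinetics", {
  spec <- step_protocol_spec(step_amps_pA = c(-200, -50),
    sag_amp_mV = 0, rebound_amp_mV = 0, noise_sd_mV = 0)
  prot <- gen_step_protocol(spec)
  s50 <- prot$steps[[2]]
  w <- slicephys:::step_windows(s50)
  ss <- mean(s50$vm[utils::tail(w$stim, round(0.1 * s50$fs))])
  expect_equal(ss - spec$rmp_mV, -50 * 143.03 / 1000, tolerance = 1e-3)
  # no sag component: response is monotone during the step
  sr <- sag_rebound(prot$steps[[1]])
  expect_lt(abs(sr$sag_mV), 0.01)
  expect_lt(abs(sr$rebound_mV), 0.01)
})
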