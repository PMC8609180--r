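test_that("PSC detection handles degenerate traces", {
  expect_error(detect_psc_events(numeric(5000), 1000), "flat trace")
  # one-sample glitch below 4 SD of the filtered trace: no events
  x <- rnorm(5000, 0, 0.5)
  x[2500] <- x[2500] - 1.2
  ev <- detect_psc_events(x, 1000, threshold_sd = 6)
  expect_equal(nrow(ev), 0L)
})

test_that("a single noiseless event is measured to kernel accuracy", {
  fs <- 10000
  x <- numeric(10 * fs)
  k <- slicephys:::biexp_kernel(fs, 1, 5)
  x[3 * fs + 1L + seq_along(k) - 1L] <- -50 * k
  ev <- detect_psc_events(x, fs)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$time_s - 3), 0.002)
  expect_lt(abs(-ev$amplitude_pA - 50) / 50, 0.05)
  ev <- event_decay_tau(x, ev, fs)
  expect_lt(abs(ev$decay_tau_ms - 5) / 5, 0.05)
})

test_that("detection timing is invariant to trace rescaling", {
  sim <- gen_psc_trace(psc_trace_spec(duration_s = 20, seed = 3))
  x <- get_channel(sim$recording)
  ev1 <- detect_psc_events(x, sim$recording$fs)
  ev2 <- detect_psc_events(5.5 * x, sim$recording$fs)
  expect_equal(ev1$time_s, ev2$time_s)
  expect_equal(ev2$amplitude_pA, 5.5 * ev1$amplitude_pA, tolerance = 1e-9)
})

test_that("the event pipeline scores well against ground truth", {
  sim <- gen_psc_trace(psc_trace_spec(duration_s = 100, rate_Hz = 2,
    amp_sigma = 0, seed = 9))
  ev <- detect_psc_events(sim$recording)
  sc <- score_psc_events(ev, sim$truth$events$time_s)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
  m <- sc$matched[[1]]
  clean <- !ev$overlapped[m[, "detected"]]
  amp_err <- abs(-ev$amplitude_pA[m[clean, "detected"]] -
    sim$truth$events$amp_pA[m[clean, "truth"]]) /
    sim$truth$events$amp_pA[m[clean, "truth"]]
  expect_lt(median(amp_err), 0.10)
  ev <- event_decay_tau(sim$recording, ev)
  ok <- ev$tau_flag == "ok"
  expect_lt(abs(median(ev$decay_tau_ms[ok]) - 5) / 5, 0.15)
})

test_that("decay constants match a simulated ensemble mean", {
  sim <- gen_psc_trace(psc_trace_spec(duration_s = 60, rate_Hz = 1.8,
    decay_ms = 4.84, noise_sd_pA = 0.75, seed = 13))
  ev <- detect_psc_events(sim$recording)
  ev <- event_decay_tau(sim$recording, ev)
  ok <- ev$tau_flag == "ok"
  expect_gt(sum(ok), 50)
  expect_lt(abs(mean(ev$decay_tau_ms[ok]) - 4.84) / 4.84, 0.10)
})

test_that("the ECDF is a valid distribution function", {
  e <- ecdf_table(c(1, 2, 3))
  expect_equal(e$prob, c(1, 2, 3) / 3)
  e2 <- ecdf_table(c(1, 1, 2))
  expect_equal(e2$prob, c(2 / 3, 1))
  expect_equal(ecdf_eval(e2, c(0.5, 1, 1.5, 2, 9)), c(0, 2/3, 2/3, 1, 1))
  expect_error(ecdf_table(numeric(0)), "no data")

  # property: monotone within [0, 1] on random data
  set.seed(21)
  for (i in 1:20) {
    v <- rnorm(sample(5:200, 1))
    et <- ecdf_table(v)
    expect_true(all(diff(et$prob) > 0))
    expect_true(et$prob[1] > 0 && dplyr::last(et$prob) == 1)
  }

  # Glivenko-Cantelli at n = 1e4
  set.seed(22)
  u <- runif(1e4)
  eu <- ecdf_table(u)
  expect_lt(max(abs(eu$prob - eu$value)), 0.03)
})

test_that("burst charge integrates baseline-subtracted current", {
  fs <- 1000
  x <- c(numeric(fs), rep(1, fs), numeric(fs))
  expect_equal(burst_auc(x, fs, c(1, 2)), 1, tolerance = 2e-3)
  ramp <- c(numeric(fs), seq(0, 1, length.out = fs), numeric(fs))
  expect_equal(burst_auc(ramp, fs, c(1, 2)), 0.5, tolerance = 2e-3)
  expect_error(burst_auc(x, fs, c(2.5, 4)), "window out of range")

  # midpoint-rule oracle on a random trace
  set.seed(30)
  r <- rnorm(3000)
  got <- burst_auc(r, fs, c(0.5, 2.5))
  seg <- r[501:2500]
  mid <- sum((seg[-1] + seg[-length(seg)]) / 2) / fs
  expect_lt(abs(got - mid) / abs(mid), 0.005)
})

test_that("reversal potentials come from the zero crossing of the IV line", {
  iv <- gen_iv_series(2, -36, seq(-70, 20, by = 10), noise_sd = 0, seed = 1)
  fit <- reversal_potential(iv$points)
  expect_equal(fit$e_rev_mV, -36, tolerance = 0.1)
  expect_equal(fit$spearman_rho, 1)
  expect_equal(glance(fit)$e_rev_mV, fit$e_rev_mV)

  # exact for noiseless lines regardless of slope sign
  iv2 <- gen_iv_series(-0.5, 10, seq(-60, 40, by = 20), noise_sd = 0, seed = 1)
  expect_equal(reversal_potential(iv2$points)$e_rev_mV, 10, tolerance = 1e-9)

  flat <- tibble::tibble(hold_mV = c(-70, -30, 10), auc = c(0, 0, 0))
  expect_error(reversal_potential(flat), "no reversal")
  expect_error(reversal_potential(iv$points[1:2, ]), "3 distinct holds")
})

test_that("reversal recovery stays within 3 mV under 10% noise", {
  holds <- seq(-70, 20, by = 10)
  noise <- 0.1 * diff(range(2 * (holds + 31)))
  errs <- vapply(1:20, function(s) {
    iv <- gen_iv_series(2, -31, holds, noise_sd = noise, seed = s)
    abs(reversal_potential(iv$points)$e_rev_mV + 31)
  }, numeric(1))
  expect_lte(median(errs), 3)
})

test_that("evoked metrics find the delayed response and flag flat traces", {
  fs <- 10000
  tr <- numeric(fs)
  stim <- 0.2
  pk <- round((stim + 0.097) * fs)
  tr[pk:(pk + 300)] <- -40 * exp(-(0:300) / 100)
  set.seed(31)
  m <- evoked_metrics(tr + rnorm(fs, 0, 0.3), fs, stim)
  expect_lt(abs(m$delayed_latency_ms - 97), 2)
  expect_false(m$flagged)

  flat <- evoked_metrics(rnorm(fs, 0, 0.3), fs, stim)
  expect_true(flat$flagged)
  expect_equal(flat$fepsp_amp, 0)
  expect_equal(flat$ps_amp, 0)

  # averaging identical responses is idempotent for the metrics
  tripl <- (tr + tr + tr) / 3
  expect_equal(evoked_metrics(tripl, fs, stim), evoked_metrics(tr, fs, stim))
})
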