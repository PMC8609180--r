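test_that("degenerate traces give no events and NaNs are rejected", {
  expect_equal(nrow(detect_bursts(numeric(20000), 2000)), 0L)
  expect_error(detect_bursts(c(rnorm(1000), NaN), 2000), "non-finite")
})

test_that("an uninterrupted sinusoid yields one near-full-record event", {
  fs <- 2000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  ev <- detect_bursts(sin(2 * pi * 5 * t), fs)
  expect_equal(nrow(ev), 1L)
  expect_gt(ev$offset_s - ev$onset_s, 28)
})

test_that("embedded bursts are recovered with accurate edges", {
  sim <- gen_coupled_lfp(coupled_lfp_spec(seed = 11))
  ev <- detect_bursts(sim$recording)
  expect_equal(nrow(ev), 3L)
  sc <- score_bursts(ev, sim$truth$bursts)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_lt(sc$onset_mae_s, 0.05)
  expect_lt(sc$offset_mae_s, 0.05)
  # events are disjoint, sorted, in bounds
  expect_true(all(diff(ev$onset_s) > 0))
  expect_true(all(ev$offset_s[-nrow(ev)] <= ev$onset_s[-1]))
  expect_true(all(ev$offset_s <= rec_duration(sim$recording)))
})

test_that("detection is invariant to positive rescaling of the trace", {
  sim <- gen_coupled_lfp(coupled_lfp_spec(duration_s = 30,
    burst_times_s = c(8, 20), burst_dur_s = 0.7, seed = 4))
  x <- get_channel(sim$recording)
  ev1 <- detect_bursts(x, 2000)
  ev2 <- detect_bursts(37.5 * x, 2000)
  expect_equal(ev1$onset_s, ev2$onset_s)
  expect_equal(ev1$offset_s, ev2$offset_s)
  expect_equal(ev2$peak_to_trough_amp, 37.5 * ev1$peak_to_trough_amp)
})

test_that("burst statistics reproduce the inter-burst-interval conventions", {
  ev <- tibble::tibble(channel = "lfp", onset_s = c(1.0, 27.2),
    offset_s = c(1.7, 27.9), peak_to_trough_amp = c(1, 1))
  st <- burst_stats(ev, 60)
  expect_equal(st$durations_s[[1]], c(0.7, 0.7))
  expect_equal(st$ibis_s[[1]], 26.2)
  expect_equal(st$rate_per_min, 60 / 26.2) # 2.29 bursts/min
  expect_equal(round(st$rate_per_min, 2), 2.29)

  single <- ev[1, ]
  st1 <- burst_stats(single, 60)
  expect_equal(length(st1$ibis_s[[1]]), 0L)
  expect_equal(st1$rate_per_min, 1)

  # 60 evenly spaced events over 600 s: both estimators agree at 6/min
  ev60 <- tibble::tibble(channel = "lfp", onset_s = seq(0, 590, by = 10),
    offset_s = seq(0.5, 590.5, by = 10), peak_to_trough_amp = 1)
  st60 <- burst_stats(ev60, 600)
  expect_equal(st60$rate_per_min, 6)
  expect_equal(st60$rate_count_per_min, 6)
})

test_that("gamma fitting recovers simulated shapes with honest CIs", {
  set.seed(3)
  x <- rgamma(500, shape = 2.45, scale = 0.3)
  fit <- fit_gamma(x)
  expect_lt(abs(fit$shape_k - 2.45) / 2.45, 0.15)
  expect_true(fit$shape_ci[1] < 2.45 && 2.45 < fit$shape_ci[2])
  expect_equal(tidy(fit)$estimate[1], fit$shape_k)

  set.seed(4)
  e <- rgamma(1000, shape = 1, scale = 2) # exponential
  fe <- fit_gamma(e)
  expect_gt(fe$shape_k, 0.9)
  expect_lt(fe$shape_k, 1.1)

  expect_error(fit_gamma(rep(2, 50)), "domain error")
  expect_error(fit_gamma(c(-1, rexp(20))), "domain error")
  expect_error(fit_gamma(rexp(5)), "insufficient sample")
})

test_that("gamma shape recovery holds at the study's sample size", {
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    x <- rgamma(119, shape = 2.45, scale = 0.27)
    abs(fit_gamma(x)$shape_k - 2.45) / 2.45
  }, numeric(1))
  expect_lte(median(errs), 0.20)
})

test_that("condition effects are percent changes against baseline", {
  base <- tibble::tibble(rate_per_min = 2, median_dur_s = 0.7, median_amp = 10)
  cond <- tibble::tibble(rate_per_min = 0.26, median_dur_s = 0.7,
    median_amp = 10)
  eff <- condition_effect(base, cond)
  expect_equal(eff$pct_change[eff$metric == "frequency"], -87)
  expect_equal(eff$pct_change[eff$metric == "duration"], 0)

  same <- condition_effect(base, base)
  expect_true(all(same$pct_change == 0))

  base0 <- dplyr::mutate(base, rate_per_min = 0)
  expect_error(condition_effect(base0, cond), "undefined normalization")
})
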