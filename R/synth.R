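#' Synthetic recordings with known ground truth
#'
#' Seeded generators that emulate the statistical structure each analysis
#' stage assumes: bursty LFPs whose low-frequency phase modulates a fast
#' band on a 1/f background, two-channel recordings with an imposed
#' inter-layer lag, voltage-clamp traces of Poisson-timed biexponential
#' postsynaptic currents with lognormal amplitudes, burst-charge vs
#' holding-potential series linear in (V - E_rev), and current-clamp step
#' responses of an RC membrane with optional sag/rebound components and
#' template action potentials.  Every generator returns the recording
#' together with a machine-readable ground-truth record sufficient to score
#' the downstream detector.
#'
#' @name synthetic-data
NULL

# 1/f^exponent background: shape a white-noise spectrum with f^(-exponent/2)
# amplitude, zero DC, then rescale to the requested SD.
one_over_f_noise <- function(n, exponent = 1, sd = 1, fs = 1) {
  w <- rnorm(n)
  if (sd == 0) return(numeric(n))
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) * fs / n
  scale <- ifelse(f > 0, f^(-exponent / 2), 0)
  y <- Re(fft(fft(w) * scale, inverse = TRUE) / n)
  y <- y - mean(y)
  y * sd / stats::sd(y)
}

# Band-limited Gaussian noise with soft (1 Hz Gaussian) band edges,
# normalized to unit RMS.
narrowband_noise <- function(n, band, fs, edge_hz = 1) {
  w <- rnorm(n)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) * fs / n
  mask <- as.numeric(f >= band[1] & f <= band[2])
  below <- f < band[1]
  above <- f > band[2]
  mask[below] <- exp(-(f[below] - band[1])^2 / (2 * edge_hz^2))
  mask[above] <- exp(-(f[above] - band[2])^2 / (2 * edge_hz^2))
  y <- Re(fft(fft(w) * mask, inverse = TRUE) / n)
  y / stats::sd(y)
}

# Raised-cosine (Tukey) taper over the first/last `frac` of a window.
tukey_taper <- function(n, frac = 0.1) {
  m <- max(1L, floor(frac * n))
  ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
  c(ramp, rep(1, n - 2L * m), rev(ramp))
}

#' Specification for a coupled bursty LFP
#'
#' @param duration_s total duration in seconds.
#' @param fs_Hz sampling rate (default 2 kHz for LFP fixtures, so the
#'   pipeline's decimation to 1 kHz has headroom).
#' @param burst_times_s burst onset times (s).
#' @param burst_dur_s burst durations (s), recycled to match.
#' @param carrier_band_Hz slow carrier band (Hz); the carrier runs at its
#'   center frequency.
#' @param coupled_amp_band_Hz fast coupled band (Hz); the modulated
#'   oscillation runs at its center frequency.
#' @param coupling_depth modulation depth in \[0, 1\]: within bursts the
#'   fast-band amplitude follows `1 + coupling_depth * cos(phase)`.
#' @param noise_exponent slope of the 1/f background.
#' @param noise_sd background SD (uV).
#' @param burst_amp carrier amplitude within bursts (uV).
#' @param coupled_amp mean amplitude of the fast coupled component (uV).
#' @param seed RNG seed.
#' @return a `coupled_lfp_spec` list.
#' @export
coupled_lfp_spec <- function(duration_s = 60, fs_Hz = 2000,
                             burst_times_s = c(10, 30, 50),
                             burst_dur_s = 0.7,
                             carrier_band_Hz = c(4, 6),
                             coupled_amp_band_Hz = c(75, 85),
                             coupling_depth = 0.8,
                             noise_exponent = 1,
                             noise_sd = 1,
                             burst_amp = max(10 * noise_sd, 1),
                             coupled_amp = max(noise_sd, 0.1),
                             seed = 1L) {
  burst_dur_s <- rep_len(burst_dur_s, length(burst_times_s))
  spec <- list(
    duration_s = duration_s, fs_Hz = fs_Hz, burst_times_s = burst_times_s,
    burst_dur_s = burst_dur_s, carrier_band_Hz = carrier_band_Hz,
    coupled_amp_band_Hz = coupled_amp_band_Hz,
    coupling_depth = coupling_depth, noise_exponent = noise_exponent,
    noise_sd = noise_sd, burst_amp = burst_amp, coupled_amp = coupled_amp,
    seed = as.integer(seed)
  )
  if (coupling_depth < 0 || coupling_depth > 1) {
    abort("coupling_depth must be in [0, 1]")
  }
  if (carrier_band_Hz[2] >= coupled_amp_band_Hz[1]) {
    abort("carrier band must lie entirely below the coupled amplitude band")
  }
  ends <- burst_times_s + burst_dur_s
  if (any(burst_times_s < 0) || any(ends > duration_s)) {
    abort("all bursts must lie within the recording duration")
  }
  if (length(burst_times_s) > 1) {
    o <- order(burst_times_s)
    if (any(burst_times_s[o][-1] < ends[o][-length(ends)])) abort("bursts overlap")
  }
  structure(spec, class = "coupled_lfp_spec")
}

#' Generate a phase-amplitude-coupled bursty LFP
#'
#' Within each burst the fast-band amplitude follows
#' `1 + coupling_depth * cos(phase_carrier)`; outside bursts the trace is
#' pure 1/f background.  Burst edges are tapered with a raised cosine.
#'
#' @param spec a [coupled_lfp_spec()].
#' @return list with `recording` (single-channel [recording], uV) and
#'   `truth` (list: `bursts` tibble with `onset_s`/`offset_s`,
#'   `carrier_hz`, `amp_hz`, `coupling_depth`, and the generating spec).
#' @export
gen_coupled_lfp <- function(spec) {
  stopifnot(inherits(spec, "coupled_lfp_spec"))
  withr::local_seed(spec$seed)
  fs <- spec$fs_Hz
  n <- round(spec$duration_s * fs)
  x <- one_over_f_noise(n, spec$noise_exponent, spec$noise_sd, fs)
  f_c <- mean(spec$carrier_band_Hz)
  f_a <- mean(spec$coupled_amp_band_Hz)
  for (i in seq_along(spec$burst_times_s)) {
    i0 <- round(spec$burst_times_s[i] * fs) + 1L
    i1 <- min(n, i0 + round(spec$burst_dur_s[i] * fs) - 1L)
    tt <- (seq(i0, i1) - i0) / fs
    phi <- 2 * pi * f_c * tt
    carrier <- spec$burst_amp * cos(phi)
    env <- (1 + spec$coupling_depth * cos(phi)) / (1 + spec$coupling_depth)
    # coupled component: band-limited noise (not a pure tone, whose
    # discrete AM sidebands would misplace the comodulogram peak)
    fast <- spec$coupled_amp * env *
      narrowband_noise(length(tt), spec$coupled_amp_band_Hz, fs)
    x[i0:i1] <- x[i0:i1] + (carrier + fast) * tukey_taper(length(tt))
  }
  rec <- recording(x, fs, units = "uV", channel_labels = "lfp")
  truth <- list(
    bursts = tibble(
      onset_s = spec$burst_times_s,
      offset_s = spec$burst_times_s + spec$burst_dur_s
    ),
    carrier_hz = f_c, amp_hz = f_a, coupling_depth = spec$coupling_depth,
    spec = spec
  )
  list(recording = rec, truth = truth)
}

#' Generate a two-channel recording with an imposed inter-channel lag
#'
#' Channel 2 is the burst component of channel 1 delayed by `lag_ms`
#' (rounded to the nearest sample; the realized value is recorded in the
#' ground truth), with independent 1/f noise added per channel.  Positive
#' `lag_ms` means channel 2 lags channel 1.
#'
#' @param spec a [coupled_lfp_spec()].
#' @param lag_ms imposed delay of channel 2 relative to channel 1 (ms).
#' @return list with `recording` (two channels, labels `L23`/`L5`) and
#'   `truth` (includes `lag_ms_requested` and realized `lag_ms`).
#' @export
gen_lagged_pair <- function(spec, lag_ms) {
  stopifnot(inherits(spec, "coupled_lfp_spec"))
  if (abs(lag_ms) >= spec$duration_s * 1000 / 2) abort("lag too large for duration")
  fs <- spec$fs_Hz
  lag_samp <- round(lag_ms / 1000 * fs)
  lag_real <- lag_samp * 1000 / fs
  # clean burst component (no noise), then per-channel independent noise
  clean_spec <- spec
  clean_spec$noise_sd <- 0
  clean <- gen_coupled_lfp(clean_spec)
  core <- get_channel(clean$recording)
  n <- length(core)
  delayed <- numeric(n)
  if (lag_samp >= 0) {
    delayed[(lag_samp + 1):n] <- core[1:(n - lag_samp)]
  } else {
    delayed[1:(n + lag_samp)] <- core[(1 - lag_samp):n]
  }
  withr::local_seed(spec$seed)
  n1 <- one_over_f_noise(n, spec$noise_exponent, spec$noise_sd, fs)
  n2 <- one_over_f_noise(n, spec$noise_exponent, spec$noise_sd, fs)
  rec <- recording(rbind(core + n1, delayed + n2), fs,
    units = "uV", channel_labels = c("L23", "L5")
  )
  truth <- c(clean$truth[c("bursts", "carrier_hz", "amp_hz")],
    list(lag_ms_requested = lag_ms, lag_ms = lag_real, spec = spec))
  list(recording = rec, truth = truth)
}

#' Specification for a synthetic postsynaptic-current trace
#'
#' @param duration_s trace duration (s).
#' @param fs_Hz sampling rate (default 10 kHz for whole-cell signals).
#' @param rate_Hz Poisson event rate.
#' @param amp_mean_pA mean event amplitude (pA, magnitude).
#' @param amp_sigma lognormal shape (sdlog) of the amplitude distribution.
#' @param rise_ms,decay_ms biexponential kernel time constants; rise < decay.
#' @param polarity `"inward"` (negative-going) or `"outward"`.
#' @param noise_sd_pA Gaussian noise SD (pA).
#' @param seed RNG seed.
#' @return a `psc_trace_spec` list.
#' @export
psc_trace_spec <- function(duration_s = 100, fs_Hz = 10000, rate_Hz = 2,
                           amp_mean_pA = 15, amp_sigma = 0.4,
                           rise_ms = 1, decay_ms = 5,
                           polarity = c("inward", "outward"),
                           noise_sd_pA = 1.5, seed = 1L) {
  polarity <- match.arg(polarity)
  if (rise_ms >= decay_ms) abort("rise_ms must be smaller than decay_ms")
  if (rate_Hz < 0) abort("rate_Hz must be nonnegative")
  structure(
    list(
      duration_s = duration_s, fs_Hz = fs_Hz, rate_Hz = rate_Hz,
      amp_mean_pA = amp_mean_pA, amp_sigma = amp_sigma, rise_ms = rise_ms,
      decay_ms = decay_ms, polarity = polarity, noise_sd_pA = noise_sd_pA,
      seed = as.integer(seed)
    ),
    class = "psc_trace_spec"
  )
}

# Biexponential kernel normalized to unit peak amplitude.
biexp_kernel <- function(fs, rise_ms, decay_ms, length_ms = NULL) {
  if (is.null(length_ms)) length_ms <- 8 * decay_ms
  t <- seq(0, length_ms / 1000, by = 1 / fs)
  k <- exp(-t / (decay_ms / 1000)) - exp(-t / (rise_ms / 1000))
  k / max(k)
}

#' Generate a voltage-clamp trace of Poisson-timed postsynaptic currents
#'
#' Events occur at Poisson times, each a biexponential kernel
#' (`rise_ms`/`decay_ms`, unit peak) scaled by a lognormal amplitude draw
#' whose mean is `amp_mean_pA`; Gaussian noise is added on top.
#'
#' @param spec a [psc_trace_spec()].
#' @return list with `recording` (single channel, pA) and `truth`
#'   (`events` tibble: `time_s`, `amp_pA` magnitude; plus kernel constants).
#' @export
gen_psc_trace <- function(spec) {
  stopifnot(inherits(spec, "psc_trace_spec"))
  withr::local_seed(spec$seed)
  fs <- spec$fs_Hz
  n <- round(spec$duration_s * fs)
  n_ev <- rpois(1, spec$rate_Hz * spec$duration_s)
  times <- sort(runif(n_ev, 0, spec$duration_s))
  mu <- log(spec$amp_mean_pA) - spec$amp_sigma^2 / 2
  amps <- rlnorm(n_ev, mu, spec$amp_sigma)
  sgn <- if (spec$polarity == "inward") -1 else 1
  kern <- biexp_kernel(fs, spec$rise_ms, spec$decay_ms)
  x <- numeric(n)
  for (i in seq_len(n_ev)) {
    i0 <- round(times[i] * fs) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    x[idx] <- x[idx] + sgn * amps[i] * kern[seq_along(idx)]
  }
  if (spec$noise_sd_pA > 0) x <- x + rnorm(n, 0, spec$noise_sd_pA)
  rec <- recording(x, fs, units = "pA", channel_labels = "Im")
  truth <- list(
    events = tibble(time_s = times, amp_pA = amps),
    rise_ms = spec$rise_ms, decay_ms = spec$decay_ms,
    polarity = spec$polarity, spec = spec
  )
  list(recording = rec, truth = truth)
}

#' Generate a burst-charge vs holding-potential series
#'
#' Simulates the linear current-voltage relation of burst charge:
#' `auc = g * (hold - e_rev) + noise`.
#'
#' @param g_nS slope conductance (nS; pA per mV).
#' @param e_rev_mV true reversal potential (mV).
#' @param holds_mV holding potentials (>= 2 distinct values).
#' @param noise_sd Gaussian noise SD on the charge values.
#' @param seed RNG seed.
#' @return list with `points` (tibble `hold_mV`, `auc`) and `truth`
#'   (`e_rev_mV`, `g_nS`).
#' @export
gen_iv_series <- function(g_nS, e_rev_mV, holds_mV, noise_sd = 0, seed = 1L) {
  if (length(unique(holds_mV)) < 2) abort("underdetermined: need >= 2 distinct holds")
  withr::local_seed(as.integer(seed))
  auc <- g_nS * (holds_mV - e_rev_mV) + rnorm(length(holds_mV), 0, noise_sd)
  list(
    points = tibble(hold_mV = as.numeric(holds_mV), auc = auc),
    truth = list(e_rev_mV = e_rev_mV, g_nS = g_nS)
  )
}

#' Synthetic action-potential template with known landmarks
#'
#' A closed-form spike waveform used both for inserting spikes into step
#' responses and for validating feature extraction: a slow sub-threshold
#' ramp (dV/dt well below the 20 mV/ms onset criterion), a quarter-sine
#' upstroke whose initial slope far exceeds it (so the detected threshold is
#' the programmed one), a half-cosine downstroke to `threshold - ahp_mV`,
#' and an exponential AHP recovery.
#'
#' @param fs sampling rate (Hz).
#' @param threshold_mV,peak_mV programmed threshold and peak.
#' @param baseline_mV pre-spike baseline.
#' @param rise_ms,fall_ms upstroke/downstroke durations.
#' @param ahp_mV AHP depth below threshold.
#' @param ahp_tau_ms AHP recovery time constant.
#' @return list with `vm` (mV), `fs`, `spike_time_s` (peak time) and
#'   `truth` (threshold, amplitude, analytic half-width, AHP).
#' @export
ap_template <- function(fs = 20000, threshold_mV = -42, peak_mV = 27,
                        baseline_mV = -70, rise_ms = 0.4, fall_ms = 0.8,
                        ahp_mV = 15, ahp_tau_ms = 20) {
  dt <- 1000 / fs # ms per sample
  hold <- rep(baseline_mV, round(20 / dt))
  ramp_ms <- 5
  ramp <- seq(baseline_mV, threshold_mV, length.out = round(ramp_ms / dt))
  tr <- seq(dt, rise_ms, by = dt)
  rise <- threshold_mV + (peak_mV - threshold_mV) * sin(pi * tr / (2 * rise_ms))
  tf <- seq(dt, fall_ms, by = dt)
  low <- threshold_mV - ahp_mV
  fall <- peak_mV - (peak_mV - low) * (1 - cos(pi * tf / fall_ms)) / 2
  # AHP recovers toward the depolarized plateau just below threshold, so
  # the post-spike minimum is the programmed AHP trough
  plateau <- threshold_mV - 5
  ta <- seq(dt, 60, by = dt)
  ahp <- plateau + (low - plateau) * exp(-ta / ahp_tau_ms)
  vm <- c(hold, ramp, rise, fall, ahp)
  peak_idx <- length(hold) + length(ramp) + length(tr)
  # analytic half-width: rise crosses the half level at rise_ms/3 before the
  # peak; the downstroke crossing follows from inverting the cosine
  half <- (threshold_mV + peak_mV) / 2
  s_fall <- fall_ms / pi * acos(1 - 2 * (peak_mV - half) / (peak_mV - low))
  hw <- (rise_ms - rise_ms / 3) + s_fall
  list(
    vm = vm, fs = fs, spike_time_s = (peak_idx - 1) / fs,
    truth = list(
      threshold_mV = threshold_mV, peak_mV = peak_mV,
      amplitude_mV = peak_mV - threshold_mV, half_width_ms = hw,
      ahp_mV = threshold_mV - low
    )
  )
}

# Additive spike deflection used when inserting APs into step responses.
ap_deflection <- function(fs, amp_mV = 80, rise_ms = 0.4, fall_ms = 0.8,
                          ahp_mV = 10, ahp_tau_ms = 15) {
  dt <- 1000 / fs
  tr <- seq(0, rise_ms, by = dt)
  rise <- amp_mV * sin(pi * tr / (2 * rise_ms))
  tf <- seq(dt, fall_ms, by = dt)
  fall <- amp_mV - (amp_mV + ahp_mV) * (1 - cos(pi * tf / fall_ms)) / 2
  ta <- seq(dt, 6 * ahp_tau_ms, by = dt)
  ahp <- -ahp_mV * exp(-ta / ahp_tau_ms)
  c(rise, fall, ahp)
}

#' Specification for a current-clamp step protocol
#'
#' Defaults are the membrane parameters of a layer II/III knockout
#' pyramidal neuron (RMP -73.62 mV, R_in 143.03 MOhm, tau 21.25 ms, sag
#' 2.57 mV and rebound 1.86 mV at -200 pA, F-I gain 0.204 Hz/pA).
#'
#' @param rmp_mV resting membrane potential.
#' @param r_in_MOhm input resistance.
#' @param tau_ms membrane time constant.
#' @param sag_amp_mV sag amplitude at the -200 pA step (0 disables).
#' @param sag_tau_ms time constant of the slow sag/rebound relaxation.
#' @param rebound_amp_mV post-offset rebound amplitude at -200 pA.
#' @param rheobase_pA smallest step current that fires.
#' @param fi_gain_Hz_per_pA slope of firing rate vs current on the axis
#'   shifted to one step below rheobase.
#' @param step_amps_pA step currents (pA), increasing.
#' @param step_dur_s step duration (s).
#' @param fs_Hz sampling rate.
#' @param noise_sd_mV Gaussian voltage noise SD.
#' @param ap_threshold_mV,ap_peak_mV programmed AP landmarks (for reference;
#'   inserted spikes are additive deflections).
#' @param seed RNG seed.
#' @return a `step_protocol_spec` list.
#' @export
step_protocol_spec <- function(rmp_mV = -73.62, r_in_MOhm = 143.03,
                               tau_ms = 21.25, sag_amp_mV = 2.57,
                               sag_tau_ms = 150, rebound_amp_mV = 1.86,
                               rheobase_pA = 100, fi_gain_Hz_per_pA = 0.204,
                               step_amps_pA = seq(-200, 300, by = 50),
                               step_dur_s = 0.5, fs_Hz = 10000,
                               noise_sd_mV = 0, ap_threshold_mV = -41.32,
                               ap_peak_mV = 27.35, seed = 1L) {
  if (step_dur_s <= 0) abort("step_dur_s must be positive")
  structure(
    list(
      rmp_mV = rmp_mV, r_in_MOhm = r_in_MOhm, tau_ms = tau_ms,
      sag_amp_mV = sag_amp_mV, sag_tau_ms = sag_tau_ms,
      rebound_amp_mV = rebound_amp_mV, rheobase_pA = rheobase_pA,
      fi_gain_Hz_per_pA = fi_gain_Hz_per_pA,
      step_amps_pA = sort(step_amps_pA), step_dur_s = step_dur_s,
      fs_Hz = fs_Hz, noise_sd_mV = noise_sd_mV,
      ap_threshold_mV = ap_threshold_mV, ap_peak_mV = ap_peak_mV,
      seed = as.integer(seed)
    ),
    class = "step_protocol_spec"
  )
}

#' A single current-clamp step response
#'
#' @param vm voltage trace (mV).
#' @param fs sampling rate (Hz).
#' @param current_pA injected step current.
#' @param pre_s,stim_s lengths of the pre-stimulus and stimulus windows (s);
#'   the remainder of the trace is the post window.
#' @return a `step_response` object.
#' @export
step_response <- function(vm, fs, current_pA, pre_s = 0.25, stim_s = 0.5) {
  structure(
    list(vm = as.numeric(vm), fs = fs, current_pA = current_pA,
      pre_s = pre_s, stim_s = stim_s),
    class = "step_response"
  )
}

#' @export
print.step_response <- function(x, ...) {
  cat(sprintf("<step_response> %+g pA, %g ms step, %d samples @ %g Hz\n",
    x$current_pA, 1000 * x$stim_s, length(x$vm), x$fs))
  invisible(x)
}

# Sag/rebound component shape: fast activation (tau) with slow relaxation
# (sag_tau); zero at stimulus onset.
slow_component <- function(t, tau_s, sag_tau_s) {
  (1 - exp(-t / tau_s)) * exp(-t / sag_tau_s)
}

#' Generate a current-clamp step protocol from an RC membrane model
#'
#' Subthreshold responses follow `RMP + I * R_in * (1 - exp(-t/tau))`.  For
#' hyperpolarizing steps an optional sag component (a transient extra
#' hyperpolarization relaxing back toward steady state) and a post-offset
#' rebound component are added; both are scaled by `|I| / 200` and their
#' internal gains are solved numerically so that the measured sag and
#' rebound at the -200 pA step equal the programmed amplitudes exactly on
#' noiseless data.  Steps at or above rheobase receive additive spike
#' deflections at a rate linear in the current above one step below
#' rheobase, so the programmed F-I gain is recovered by the shifted fit.
#'
#' @param spec a [step_protocol_spec()].
#' @return list with `steps` (list of [step_response()]) and `truth`
#'   (membrane parameters, per-step spike counts and times).
#' @export
gen_step_protocol <- function(spec) {
  stopifnot(inherits(spec, "step_protocol_spec"))
  withr::local_seed(spec$seed)
  fs <- spec$fs_Hz
  pre_s <- 0.25; stim_s <- spec$step_dur_s; post_s <- 0.75
  n_pre <- round(pre_s * fs); n_stim <- round(stim_s * fs)
  n_post <- round(post_s * fs)
  t_stim <- (seq_len(n_stim) - 1) / fs
  t_post <- (seq_len(n_post) - 1) / fs
  tau_s <- spec$tau_ms / 1000
  sag_tau_s <- spec$sag_tau_ms / 1000
  incr <- if (length(spec$step_amps_pA) > 1) {
    min(diff(sort(unique(spec$step_amps_pA))))
  } else {
    50
  }
  shift_origin <- spec$rheobase_pA - incr

  # solve component gains once at the -200 pA reference step
  ref_dv <- -200 * spec$r_in_MOhm / 1000
  base_stim_ref <- ref_dv * (1 - exp(-t_stim / tau_s))
  comp_stim <- slow_component(t_stim, tau_s, sag_tau_s)
  sag_gain <- 0
  if (spec$sag_amp_mV > 0) {
    f <- function(k) {
      v <- base_stim_ref - k * comp_stim
      ss <- mean(v[t_stim >= stim_s - 0.1])
      (ss - min(v)) - spec$sag_amp_mV
    }
    sag_gain <- stats::uniroot(f, c(0, 10 * spec$sag_amp_mV), tol = 1e-10)$root
  }
  base_post_ref <- (ref_dv - sag_gain * comp_stim[n_stim]) * exp(-t_post / tau_s)
  comp_post <- slow_component(t_post, tau_s, sag_tau_s)
  reb_gain <- 0
  if (spec$rebound_amp_mV > 0) {
    f <- function(k) {
      max(base_post_ref[t_post <= 0.5] + k * comp_post[t_post <= 0.5]) -
        spec$rebound_amp_mV
    }
    hi <- (spec$rebound_amp_mV + abs(ref_dv) + 1) / max(comp_post)
    reb_gain <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  }

  steps <- list()
  counts <- integer(length(spec$step_amps_pA))
  spike_times <- vector("list", length(spec$step_amps_pA))
  defl <- ap_deflection(fs)
  for (j in seq_along(spec$step_amps_pA)) {
    I <- spec$step_amps_pA[j]
    dv <- I * spec$r_in_MOhm / 1000
    hyper_scale <- max(0, -I) / 200
    v_stim <- dv * (1 - exp(-t_stim / tau_s)) -
      hyper_scale * sag_gain * comp_stim
    v_post <- v_stim[n_stim] * exp(-t_post / tau_s) +
      hyper_scale * reb_gain * comp_post
    vm <- spec$rmp_mV + c(numeric(n_pre), v_stim, v_post)
    st <- numeric(0)
    if (I >= spec$rheobase_pA && spec$fi_gain_Hz_per_pA > 0) {
      rate <- spec$fi_gain_Hz_per_pA * (I - shift_origin)
      k <- max(1L, round(rate * stim_s))
      st <- pre_s + (seq_len(k) - 0.5) / k * stim_s
      for (ts in st) {
        i0 <- round(ts * fs) + 1L
        idx <- i0:min(length(vm), i0 + length(defl) - 1L)
        vm[idx] <- vm[idx] + defl[seq_along(idx)]
      }
      counts[j] <- k
    }
    if (spec$noise_sd_mV > 0) vm <- vm + rnorm(length(vm), 0, spec$noise_sd_mV)
    spike_times[[j]] <- st
    steps[[j]] <- step_response(vm, fs, I, pre_s, stim_s)
  }
  truth <- list(
    rmp_mV = spec$rmp_mV, r_in_MOhm = spec$r_in_MOhm, tau_ms = spec$tau_ms,
    sag_mV = spec$sag_amp_mV, rebound_mV = spec$rebound_amp_mV,
    rheobase_pA = spec$rheobase_pA,
    fi_gain_Hz_per_pA = spec$fi_gain_Hz_per_pA,
    shift_origin_pA = shift_origin,
    steps = tibble(
      current_pA = spec$step_amps_pA, n_spikes = counts,
      spike_times = spike_times
    ),
    spec = spec
  )
  list(steps = steps, truth = truth)
}
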