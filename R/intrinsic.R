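#' Detect action potentials in a current-clamp voltage trace
#'
#' Spikes are local maxima that exceed `min_peak_mV` and have a prominence
#' of at least `min_prominence_mV` (height above the higher of the two
#' saddle minima separating the peak from taller terrain).  Peaks closer
#' than the refractory period are resolved in favor of the taller one.
#'
#' @param vm voltage samples (mV) or a [recording].
#' @param fs sampling rate (Hz); >= 5 kHz recommended for AP fidelity (a
#'   warning is issued below that).
#' @param min_prominence_mV minimum peak prominence.
#' @param min_peak_mV minimum absolute peak voltage.
#' @param refractory_ms minimum separation between spikes.
#' @param channel channel when `vm` is a recording.
#' @return numeric vector of spike (peak) times in seconds; empty if none.
#' @export
detect_spikes <- function(vm, fs = NULL, min_prominence_mV = 20,
                          min_peak_mV = -10, refractory_ms = 1,
                          channel = 1L) {
  s <- resolve_signal(vm, fs, channel)
  vm <- s$x; fs <- s$fs
  if (fs < 5000) warn("fs below 5 kHz: action-potential features may be undersampled")
  n <- length(vm)
  if (n < 3) return(numeric(0))
  core <- vm[2:(n - 1)]
  is_peak <- core > vm[1:(n - 2)] & core >= vm[3:n] & core >= min_peak_mV
  cand <- which(is_peak) + 1L
  if (length(cand) == 0) return(numeric(0))
  prom <- vapply(cand, function(i) peak_prominence(vm, i), numeric(1))
  cand <- cand[prom >= min_prominence_mV]
  if (length(cand) == 0) return(numeric(0))
  # enforce refractory period, keeping the taller peak
  refr <- round(refractory_ms / 1000 * fs)
  keep <- rep(TRUE, length(cand))
  last <- 1L
  for (i in seq_along(cand)[-1]) {
    if (cand[i] - cand[last] < refr) {
      if (vm[cand[i]] > vm[cand[last]]) {
        keep[last] <- FALSE
        last <- i
      } else {
        keep[i] <- FALSE
      }
    } else {
      last <- i
    }
  }
  (cand[keep] - 1L) / fs
}

# Topographic prominence of the peak at index i.
peak_prominence <- function(vm, i) {
  h <- vm[i]
  left <- vm[seq_len(i - 1L)]
  right <- vm[seq(i + 1L, length(vm))]
  key <- function(side) {
    higher <- which(side >= h)
    if (length(higher) == 0) return(min(side))
    # nearest higher sample bounds the saddle search
    min(side[seq(
      if (identical(side, left)) max(higher) else 1L,
      if (identical(side, left)) length(side) else min(higher)
    )])
  }
  lmin <- if (length(left)) key(left) else h
  rmin <- if (length(right)) key(right) else h
  h - max(lmin, rmin)
}

#' Action-potential features of a single spike
#'
#' Threshold is the onset point where dV/dt first exceeds
#' `dvdt_thresh_mV_per_ms` (default 20 mV/ms) on the upstroke
#' (`mode = "onset"`), or the point of steepest rise (`mode = "max_dvdt"`).
#' Amplitude is threshold to peak; half-width is the trace width at the
#' voltage halfway between threshold and peak (linear interpolation at both
#' crossings); AHP is threshold minus the post-spike minimum within
#' `ahp_window_ms`.
#'
#' @param vm voltage samples (mV) or a [recording].
#' @param fs sampling rate (Hz).
#' @param spike_time_s peak time of an isolated spike (s), e.g. from
#'   [detect_spikes()].
#' @param dvdt_thresh_mV_per_ms onset criterion.
#' @param mode threshold definition, `"onset"` or `"max_dvdt"`.
#' @param search_ms how far before the peak to search for the threshold.
#' @param ahp_window_ms post-peak window for the AHP minimum.
#' @param channel channel when `vm` is a recording.
#' @return one-row tibble: `threshold_mV`, `peak_mV`, `amplitude_mV`,
#'   `half_width_ms`, `ahp_mV`, `flagged` (TRUE when the spike is clipped
#'   or a landmark could not be located; features then NaN).
#' @export
ap_features <- function(vm, fs = NULL, spike_time_s,
                        dvdt_thresh_mV_per_ms = 20,
                        mode = c("onset", "max_dvdt"), search_ms = 5,
                        ahp_window_ms = 50, channel = 1L) {
  mode <- match.arg(mode)
  s <- resolve_signal(vm, fs, channel)
  vm <- s$x; fs <- s$fs
  bad <- tibble(
    threshold_mV = NaN, peak_mV = NaN, amplitude_mV = NaN,
    half_width_ms = NaN, ahp_mV = NaN, flagged = TRUE
  )
  pk <- round(spike_time_s * fs) + 1L
  n <- length(vm)
  if (pk < 3L || pk > n - 2L) return(bad)
  i0 <- max(1L, pk - round(search_ms / 1000 * fs))
  up <- vm[i0:pk]
  dvdt <- diff(up) * fs / 1000 # mV/ms
  onset <- if (mode == "onset") {
    ap_onset(up, fs, dvdt, dvdt_thresh_mV_per_ms)
  } else {
    k <- which.max(dvdt)
    list(idx = k, value = up[k])
  }
  if (is.null(onset) || is.na(onset$idx)) return(bad)
  thr_i <- i0 + onset$idx - 1L
  threshold <- onset$value
  peak <- vm[pk]
  if (peak <= threshold) return(bad)
  half <- (threshold + peak) / 2
  # rising crossing (interpolated)
  r <- thr_i
  while (r < pk && vm[r + 1L] < half) r <- r + 1L
  t_rise <- r + (half - vm[r]) / (vm[r + 1L] - vm[r])
  # falling crossing
  f <- pk
  lim <- min(n, pk + round(ahp_window_ms / 1000 * fs))
  while (f < lim && vm[f + 1L] > half) f <- f + 1L
  if (f >= lim) return(bad) # clipped / truncated spike
  t_fall <- f + (half - vm[f]) / (vm[f + 1L] - vm[f])
  hw <- (t_fall - t_rise) * 1000 / fs
  # AHP trough: locate on a lightly smoothed trace (the raw extremum of a
  # long noisy window is noise-biased), then read the value from a local
  # quadratic fit, which averages the noise without the smoothing bias
  post <- vm[pk:lim]
  ahp_min <- trough_value(post, fs)
  tibble(
    threshold_mV = threshold, peak_mV = peak,
    amplitude_mV = peak - threshold, half_width_ms = hw,
    ahp_mV = threshold - ahp_min, flagged = FALSE
  )
}

# Noise-tolerant minimum of a trace segment: approximate trough from a
# short moving average, then a quadratic fit over +/- 0.5 ms around it.
trough_value <- function(seg, fs) {
  n <- length(seg)
  k <- max(1L, round(0.25e-3 * fs))
  sm <- if (n > k) {
    as.numeric(stats::filter(seg, rep(1 / k, k), sides = 2))
  } else {
    seg
  }
  j0 <- which.min(replace(sm, is.na(sm), Inf))
  # fit only the neighborhood at the trough's level: the approach can be
  # far steeper on one side than the other
  base_v <- sm[j0]
  lo <- j0
  while (lo > 1L && !is.na(sm[lo - 1L]) && sm[lo - 1L] <= base_v + 1) lo <- lo - 1L
  hi <- j0
  while (hi < n && !is.na(sm[hi + 1L]) && sm[hi + 1L] <= base_v + 1) hi <- hi + 1L
  w <- max(2L, round(0.5e-3 * fs))
  idx <- max(lo, j0 - w):min(hi, j0 + w)
  if (length(idx) < 5L) return(min(sm, na.rm = TRUE))
  tt <- idx - j0
  fit <- lm(seg[idx] ~ tt + I(tt^2))
  cf <- coef(fit)
  vertex <- if (is.finite(cf[3]) && cf[3] > 0) -cf[2] / (2 * cf[3]) else 0
  vertex <- min(max(vertex, min(tt)), max(tt))
  unname(cf[1] + cf[2] * vertex + cf[3] * vertex^2)
}

# Onset-criterion threshold with a noise-tolerant read-out.  The crossing
# is located on a slope measured over ~0.25 ms (voltage noise cannot
# trigger it); the threshold voltage is then read from the intersection
# of a line fit to the subthreshold ramp with a line fit to the steepest
# part of the upstroke -- exact at a noiseless kink, noise-averaged
# otherwise.
ap_onset <- function(up, fs, dvdt, dvdt_thresh) {
  n <- length(up)
  span <- max(1L, round(0.25e-3 * fs))
  i <- if (n - 1L > span) {
    sm <- (up[(1 + span):n] - up[1:(n - span)]) * fs / (1000 * span)
    which(sm >= dvdt_thresh)[1]
  } else {
    which(dvdt >= dvdt_thresh)[1]
  }
  if (is.na(i)) return(list(idx = NA_integer_, value = NA_real_))
  hi <- min(length(dvdt), i + span)
  m <- i - 1L + which.max(dvdt[i:hi]) # steepest interval near the crossing
  # upstroke fit over the samples still near the maximal slope
  s_lo <- m
  while (s_lo > i && dvdt[s_lo - 1L] >= 0.5 * dvdt[m]) s_lo <- s_lo - 1L
  s_hi <- m
  while (s_hi < min(length(dvdt), m + 2L * span) &&
    dvdt[s_hi + 1L] >= 0.5 * dvdt[m]) s_hi <- s_hi + 1L
  s_idx <- s_lo:min(n, s_hi + 1L)
  p_idx <- max(1L, i - 6L * span):i
  if (length(p_idx) < 2L || length(s_idx) < 2L) {
    return(list(idx = i, value = up[i]))
  }
  a <- coef(lm(up[p_idx] ~ p_idx))
  b <- coef(lm(up[s_idx] ~ s_idx))
  if (!is.finite(b[2]) || abs(b[2] - a[2]) < 1e-12) {
    return(list(idx = i, value = up[i]))
  }
  t_star <- (a[1] - b[1]) / (b[2] - a[2])
  t_star <- min(max(t_star, p_idx[1]), s_idx[length(s_idx)])
  list(idx = max(1L, min(n, round(t_star))),
    value = unname(a[1] + a[2] * t_star))
}

step_windows <- function(step) {
  fs <- step$fs
  n_pre <- round(step$pre_s * fs)
  n_stim <- round(step$stim_s * fs)
  list(
    pre = seq_len(n_pre),
    stim = seq(n_pre + 1L, n_pre + n_stim),
    post = seq(n_pre + n_stim + 1L, length(step$vm)),
    fs = fs, n_pre = n_pre, n_stim = n_stim
  )
}

step_has_spikes <- function(step) {
  w <- step_windows(step)
  length(detect_spikes(step$vm[w$stim], step$fs)) > 0
}

#' Passive membrane properties from a step protocol
#'
#' RMP is the mean of the 50 ms preceding the stimulus (averaged across
#' sweeps); input resistance is the least-squares slope of the
#' steady-state voltage deflection vs injected current over subthreshold
#' steps; the time constant comes from a single-exponential fit to the
#' first `tau_fit_ms` of the smallest hyperpolarizing response.
#'
#' @param steps list of [step_response()] objects.
#' @param tau_fit_ms initial-segment length for the tau fit.
#' @return one-row tibble: `rmp_mV`, `r_in_MOhm`, `tau_ms`, `n_subthreshold`.
#' @export
passive_props <- function(steps, tau_fit_ms = 60) {
  sub <- Filter(function(s) !step_has_spikes(s), steps)
  if (length(sub) < 2) abort("cannot fit: need >= 2 subthreshold steps")
  rmp <- mean(vapply(steps, function(s) {
    w <- step_windows(s)
    idx <- w$pre[w$pre > w$n_pre - round(0.05 * s$fs)]
    mean(s$vm[idx])
  }, numeric(1)))
  dv <- vapply(sub, function(s) {
    w <- step_windows(s)
    ss <- mean(s$vm[w$stim[w$stim > max(w$stim) - round(0.1 * s$fs)]])
    pre <- mean(s$vm[w$pre[w$pre > w$n_pre - round(0.05 * s$fs)]])
    ss - pre
  }, numeric(1))
  ii <- vapply(sub, function(s) s$current_pA, numeric(1))
  r_in <- coef(lm(dv ~ ii))[["ii"]] * 1000 # mV/pA -> MOhm
  # tau from the smallest hyperpolarizing step
  hyper <- sub[vapply(sub, function(s) s$current_pA < 0, logical(1))]
  tau <- NA_real_
  if (length(hyper) > 0) {
    s <- hyper[[which.min(vapply(hyper, function(s) abs(s$current_pA), numeric(1)))]]
    w <- step_windows(s)
    nfit <- round(tau_fit_ms / 1000 * s$fs)
    seg <- s$vm[w$stim[seq_len(min(nfit, length(w$stim)))]]
    tt <- (seq_along(seg) - 1) / s$fs * 1000
    v0 <- seg[1]
    dv_amp <- seg[length(seg)] - v0
    fit <- tryCatch(
      minpack.lm::nlsLM(seg ~ v0f + a * (1 - exp(-tt / tau)),
        start = list(v0f = v0, a = dv_amp, tau = 15),
        lower = c(-Inf, -Inf, 1e-3)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) tau <- coef(fit)[["tau"]]
  }
  tibble(rmp_mV = rmp, r_in_MOhm = r_in, tau_ms = tau,
    n_subthreshold = length(sub))
}

#' Sag and post-inhibitory rebound of a hyperpolarizing step
#'
#' Sag is the steady-state voltage (mean of the last 100 ms of the step)
#' minus the most negative deflection during the step.  Rebound is the most
#' positive deflection within `rebound_window_ms` after stimulus offset
#' minus the mean of the 50 ms preceding the stimulus.  If spikes occur in
#' the rebound window, the rebound is measured to the first spike's
#' threshold and flagged.
#'
#' @param step a [step_response()], conventionally the -200 pA step.
#' @param rebound_window_ms post-offset search window.
#' @return one-row tibble: `sag_mV`, `rebound_mV`, `current_pA`, `flagged`.
#' @export
sag_rebound <- function(step, rebound_window_ms = 500) {
  w <- step_windows(step)
  fs <- step$fs
  stim_v <- step$vm[w$stim]
  ss <- mean(stim_v[seq(length(stim_v) - round(0.1 * fs) + 1L, length(stim_v))])
  sag <- ss - min(stim_v)
  pre_v <- mean(step$vm[w$pre[w$pre > w$n_pre - round(0.05 * fs)]])
  post_idx <- w$post[seq_len(min(length(w$post), round(rebound_window_ms / 1000 * fs)))]
  post_v <- step$vm[post_idx]
  flagged <- FALSE
  sp <- detect_spikes(post_v, fs)
  if (length(sp) > 0) {
    flagged <- TRUE
    feat <- ap_features(post_v, fs, sp[1])
    rebound <- (if (is.finite(feat$threshold_mV)) feat$threshold_mV else
      max(post_v)) - pre_v
  } else {
    rebound <- max(post_v) - pre_v
  }
  tibble(sag_mV = sag, rebound_mV = rebound,
    current_pA = step$current_pA, flagged = flagged)
}

#' Frequency-current (F-I) analysis with the below-rheobase shift
#'
#' Counts spikes per depolarizing step (rate = count / step duration);
#' rheobase is the smallest current with at least one spike.  The F-I curve
#' is re-indexed relative to one current increment below rheobase, and the
#' slope is the least-squares slope of rate vs current over the shifted
#' non-negative currents (which include the silent step just below
#' rheobase).
#'
#' @param steps list of [step_response()] objects with increasing currents.
#' @return object of class `fi_fit`: `fi` tibble (`current_pA`,
#'   `n_spikes`, `rate_Hz`, `shifted_pA`), `rheobase_pA`,
#'   `slope_Hz_per_pA`, `shift_origin_pA`.  If no step fires, rheobase and
#'   slope are NA with a flag.
#' @export
fi_analysis <- function(steps) {
  cur <- vapply(steps, function(s) s$current_pA, numeric(1))
  o <- order(cur)
  steps <- steps[o]; cur <- cur[o]
  counts <- vapply(steps, function(s) {
    w <- step_windows(s)
    length(detect_spikes(s$vm[w$stim], s$fs))
  }, numeric(1))
  dur <- steps[[1]]$stim_s
  rate <- counts / dur
  fi <- tibble(current_pA = cur, n_spikes = counts, rate_Hz = rate)
  firing <- which(counts >= 1)
  if (length(firing) == 0) {
    return(structure(
      list(fi = fi, rheobase_pA = NA_real_, slope_Hz_per_pA = NA_real_,
        shift_origin_pA = NA_real_, flagged = TRUE),
      class = "fi_fit"
    ))
  }
  rheo <- cur[min(firing)]
  incr <- if (length(cur) > 1) min(diff(cur)) else rheo
  origin <- rheo - incr
  fi$shifted_pA <- fi$current_pA - origin
  sel <- fi$shifted_pA >= 0
  slope <- coef(lm(rate_Hz ~ shifted_pA, data = fi[sel, ]))[["shifted_pA"]]
  structure(
    list(fi = fi, rheobase_pA = rheo, slope_Hz_per_pA = slope,
      shift_origin_pA = origin, flagged = FALSE),
    class = "fi_fit"
  )
}

#' @export
print.fi_fit <- function(x, ...) {
  if (x$flagged) {
    cat("<fi_fit> no spikes at any step; rheobase undefined\n")
  } else {
    cat(sprintf(
      "<fi_fit> rheobase %g pA, slope %.4f Hz/pA (origin %g pA)\n",
      x$rheobase_pA, x$slope_Hz_per_pA, x$shift_origin_pA
    ))
  }
  invisible(x)
}

#' Full intrinsic-property extraction from a step protocol
#'
#' Convenience wrapper combining [passive_props()], [sag_rebound()] (at the
#' step closest to `sag_current_pA`), [fi_analysis()] and AP features of
#' the first spike at rheobase.
#'
#' @param steps list of [step_response()] objects.
#' @param sag_current_pA current at which sag/rebound are measured.
#' @return object of class `membrane_props`: one-row `summary` tibble
#'   (`rmp_mV`, `r_in_MOhm`, `tau_ms`, `sag_mV`, `rebound_mV`,
#'   `rheobase_pA`, `fi_slope_Hz_per_pA`, AP features) plus the `fi_fit`.
#' @export
membrane_props <- function(steps, sag_current_pA = -200) {
  pp <- passive_props(steps)
  cur <- vapply(steps, function(s) s$current_pA, numeric(1))
  sag_step <- steps[[which.min(abs(cur - sag_current_pA))]]
  sr <- sag_rebound(sag_step)
  fi <- fi_analysis(steps)
  ap <- tibble(threshold_mV = NA_real_, amplitude_mV = NA_real_,
    half_width_ms = NA_real_, ahp_mV = NA_real_)
  if (!fi$flagged) {
    rheo_step <- steps[[which(cur == fi$rheobase_pA)[1]]]
    w <- step_windows(rheo_step)
    sp <- detect_spikes(rheo_step$vm, rheo_step$fs)
    sp <- sp[sp * rheo_step$fs >= min(w$stim)]
    if (length(sp) > 0) {
      f <- ap_features(rheo_step$vm, rheo_step$fs, sp[1])
      ap <- f[, c("threshold_mV", "amplitude_mV", "half_width_ms", "ahp_mV")]
    }
  }
  structure(
    list(
      summary = dplyr::bind_cols(
        pp[, c("rmp_mV", "r_in_MOhm", "tau_ms")],
        sr[, c("sag_mV", "rebound_mV")],
        tibble(rheobase_pA = fi$rheobase_pA,
          fi_slope_Hz_per_pA = fi$slope_Hz_per_pA),
        ap
      ),
      fi = fi
    ),
    class = "membrane_props"
  )
}

#' @export
print.membrane_props <- function(x, ...) {
  cat("<membrane_props>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
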