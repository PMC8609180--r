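#' Detect postsynaptic-current events in a voltage-clamp trace
#'
#' Detection runs on the band-passed trace (see [psc_bandpass()]); the
#' threshold is `threshold_sd` times the SD of the filtered trace, in the
#' configured polarity, so detection is invariant to positive rescaling.
#' For each crossing, the baseline is the mean of the raw trace over the
#' preceding `baseline_ms`, the peak is the extremum of the raw trace
#' within `window_ms` after the crossing, and the amplitude is peak minus
#' baseline (negative for inward events).  Events whose windows overlap are
#' flagged `overlapped`; the scan resumes after the current peak.
#'
#' @param x numeric current samples (pA) at 1 kHz, or a [recording]
#'   (decimated internally to 1 kHz if faster).
#' @param fs sampling rate (Hz).
#' @param polarity `"inward"` (negative-going) or `"outward"`.
#' @param threshold_sd detection threshold in filtered-trace SDs.
#' @param window_ms peak-search window after the threshold crossing.
#' @param baseline_ms baseline window before the crossing.
#' @param channel channel when `x` is a recording.
#' @return tibble of events: `time_s` (threshold crossing), `peak_s`,
#'   `amplitude_pA`, `baseline_pA`, `overlapped`, `decay_tau_ms` (NA until
#'   [event_decay_tau()] is applied).
#' @examples
#' sim <- gen_psc_trace(psc_trace_spec(duration_s = 20, seed = 9))
#' ev <- detect_psc_events(sim$recording)
#' @export
detect_psc_events <- function(x, fs = NULL, polarity = c("inward", "outward"),
                              threshold_sd = 4, window_ms = 100,
                              baseline_ms = 10, channel = 1L) {
  polarity <- match.arg(polarity)
  s <- resolve_signal(x, fs, channel)
  x <- s$x; fs <- s$fs
  if (fs > 1000) {
    x <- decimate_to(x, fs, 1000)
    fs <- 1000
  }
  if (length(x) < fs) abort("trace must be at least 1 s long")
  filt <- psc_bandpass(x, fs)
  sd_f <- sd(filt)
  if (sd_f == 0) abort("flat trace")
  thr <- threshold_sd * sd_f
  exceed <- if (polarity == "inward") filt < -thr else filt > thr
  n <- length(x)
  w <- round(window_ms / 1000 * fs)
  bw <- round(baseline_ms / 1000 * fs)
  ext <- if (polarity == "inward") which.min else which.max
  # fresh threshold crossings only (rising edges of the exceedance mask)
  starts <- which(exceed & !c(FALSE, exceed[-n]))
  cross <- peak_i <- integer(0)
  resume <- 0L
  for (k in seq_along(starts)) {
    i <- starts[k]
    if (i <= resume) next
    # peak search runs to the window end but stops at the next fresh
    # crossing, so closely spaced events are not fused into one
    j <- min(n, i + w)
    if (k < length(starts)) j <- min(j, starts[k + 1L] - 1L)
    pk <- i - 1L + ext(x[i:j])
    cross <- c(cross, i)
    peak_i <- c(peak_i, pk)
    resume <- pk # next detection resumes after the current peak
  }
  if (length(cross) == 0) {
    return(tibble(
      time_s = numeric(), peak_s = numeric(), amplitude_pA = numeric(),
      baseline_pA = numeric(), overlapped = logical(),
      decay_tau_ms = numeric()
    ))
  }
  baseline <- vapply(cross, function(ci) {
    mean(x[max(1L, ci - bw):max(1L, ci - 1L)])
  }, numeric(1))
  amp <- x[peak_i] - baseline
  overl <- rep(FALSE, length(cross))
  if (length(cross) > 1) {
    gap_next <- c(diff(cross), Inf) < w
    overl <- gap_next | c(FALSE, gap_next[-length(gap_next)])
  }
  tibble(
    time_s = (cross - 1L) / fs,
    peak_s = (peak_i - 1L) / fs,
    amplitude_pA = amp,
    baseline_pA = baseline,
    overlapped = overl,
    decay_tau_ms = NA_real_
  )
}

#' Fit the decay time constant of a detected event
#'
#' Single-exponential least-squares fit of the raw trace from the event
#' peak toward its baseline, over `fit_window_ms` or until the next event,
#' whichever comes first.  The fit starts `skip_ms` after the peak, where
#' the rising phase no longer contaminates the decay.  Overlapped events
#' and failed fits return `NaN` with a flag.
#'
#' @param x raw trace (pA) at 1 kHz, or a [recording].
#' @param events tibble from [detect_psc_events()].
#' @param fs sampling rate.
#' @param fit_window_ms maximum fit window after the peak.
#' @param skip_ms dead time between the peak and the start of the fit.
#' @param channel channel when `x` is a recording.
#' @return `events` with `decay_tau_ms` filled in and a `tau_flag` column
#'   (`"ok"`, `"overlapped"`, `"fit_failed"`).
#' @export
event_decay_tau <- function(x, events, fs = NULL, fit_window_ms = 50,
                            skip_ms = 2, channel = 1L) {
  s <- resolve_signal(x, fs, channel)
  x <- s$x; fs <- s$fs
  if (fs > 1000) {
    x <- decimate_to(x, fs, 1000)
    fs <- 1000
  }
  n <- length(x)
  taus <- rep(NaN, nrow(events))
  flags <- rep("ok", nrow(events))
  for (i in seq_len(nrow(events))) {
    if (isTRUE(events$overlapped[i])) {
      flags[i] <- "overlapped"
      next
    }
    p0 <- round(events$peak_s[i] * fs) + 1L + round(skip_ms / 1000 * fs)
    pend <- min(n, p0 + round(fit_window_ms / 1000 * fs))
    if (i < nrow(events)) {
      pend <- min(pend, round(events$time_s[i + 1] * fs))
    }
    if (pend - p0 < 5L) {
      flags[i] <- "fit_failed"
      next
    }
    seg <- x[p0:pend] - events$baseline_pA[i]
    tt <- (seq_along(seg) - 1 + round(skip_ms / 1000 * fs)) / fs * 1000 # ms from peak
    a0 <- events$amplitude_pA[i]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        seg ~ A * exp(-tt / tau),
        start = list(A = a0, tau = 5),
        lower = c(A = -Inf, tau = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 100)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      flags[i] <- "fit_failed"
    } else {
      tau <- coef(fit)[["tau"]]
      if (tau <= 0 || tau > 10 * fit_window_ms) {
        flags[i] <- "fit_failed"
      } else {
        taus[i] <- tau
      }
    }
  }
  events$decay_tau_ms <- taus
  events$tau_flag <- flags
  events
}

#' Empirical cumulative distribution of event measures
#'
#' Standard right-continuous ECDF (the Kaplan-Meier estimate with no
#' censoring reduces to this): evaluation below the minimum gives 0, at or
#' above the maximum gives 1.
#'
#' @param values nonempty numeric vector.
#' @return object of class `ecdf_table`: tibble with `value` (sorted
#'   unique) and `prob` (cumulative probability after each jump).
#' @export
ecdf_table <- function(values) {
  if (length(values) == 0) abort("no data")
  v <- sort(values)
  u <- unique(v)
  p <- cumsum(tabulate(match(v, u))) / length(v)
  out <- tibble(value = u, prob = p)
  class(out) <- c("ecdf_table", class(out))
  out
}

#' Evaluate an ECDF at arbitrary points
#' @param e an `ecdf_table`.
#' @param q numeric query points.
#' @return cumulative probabilities at `q`.
#' @export
ecdf_eval <- function(e, q) {
  vapply(q, function(x) {
    i <- findInterval(x, e$value)
    if (i == 0) 0 else e$prob[i]
  }, numeric(1))
}

#' Charge (area under the curve) of a burst window
#'
#' Trapezoidal integral of the baseline-subtracted trace over a time
#' window.
#'
#' @param x trace (pA) or a [recording].
#' @param fs sampling rate (Hz).
#' @param window numeric length-2, `(t0, t1)` in seconds, half-open.
#' @param baseline scalar baseline to subtract, or a length-2 time window
#'   whose mean is used.
#' @param channel channel when `x` is a recording.
#' @return charge in pA * s.
#' @export
burst_auc <- function(x, fs = NULL, window, baseline = 0, channel = 1L) {
  s <- resolve_signal(x, fs, channel)
  x <- s$x; fs <- s$fs
  i0 <- round(window[1] * fs) + 1L
  i1 <- round(window[2] * fs)
  if (i0 < 1L || i1 > length(x) || i1 <= i0) abort("window out of range")
  b <- if (length(baseline) == 2) {
    j0 <- max(1L, round(baseline[1] * fs) + 1L)
    j1 <- min(length(x), round(baseline[2] * fs))
    mean(x[j0:j1])
  } else {
    baseline
  }
  seg <- x[i0:i1] - b
  pracma::trapz(seq_along(seg) / fs, seg)
}

#' Reversal potential from a charge vs holding-potential series
#'
#' Least-squares line `auc = a * V + b`; the reversal potential is the
#' zero crossing `-b / a`.  Spearman correlation across the points is
#' reported as in the underlying current-voltage analysis.
#'
#' @param points tibble with columns `hold_mV` and `auc` (>= 3 distinct
#'   holds).
#' @param slope_tol relative tolerance below which the slope is considered
#'   zero and no reversal is reported.
#' @return object of class `iv_fit`: `points`, `slope`, `intercept`,
#'   `e_rev_mV`, `spearman_rho`, `p`.
#' @examples
#' iv <- gen_iv_series(2, -36, seq(-70, 20, by = 10))
#' reversal_potential(iv$points)$e_rev_mV
#' @export
reversal_potential <- function(points, slope_tol = 1e-10) {
  if (length(unique(points$hold_mV)) < 3) abort("need >= 3 distinct holds")
  fit <- lm(auc ~ hold_mV, data = points)
  a <- coef(fit)[["hold_mV"]]
  b <- coef(fit)[["(Intercept)"]]
  scale <- sd(points$auc) / max(1e-12, diff(range(points$hold_mV)))
  if (abs(a) <= slope_tol * max(1, scale)) abort("no reversal in range: slope ~ 0")
  ct <- suppressWarnings(
    cor.test(points$hold_mV, points$auc, method = "spearman")
  )
  structure(
    list(
      points = points, slope = a, intercept = b, e_rev_mV = -b / a,
      spearman_rho = unname(ct$estimate), p = ct$p.value
    ),
    class = "iv_fit"
  )
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf(
    "<iv_fit> E_rev = %.2f mV (slope %.4g /mV), Spearman rho %.3f (p = %.3g), n = %d\n",
    x$e_rev_mV, x$slope, x$spearman_rho, x$p, nrow(x$points)
  ))
  invisible(x)
}

#' Evoked field-response metrics
#'
#' Measures the initial field EPSP (baseline-to-peak of the first negative
#' deflection in `fepsp_window_ms`), the population-spike amplitude
#' (peak-to-trough within that window), and the latency of the delayed
#' response (largest negative peak within `delayed_window_ms`), all
#' relative to stimulus onset.  The stimulus artifact window (first
#' `artifact_ms`) is excluded.  If no post-stimulus deflection exceeds
#' `noise_k` baseline SDs, amplitudes are zero with a flag.
#'
#' @param x trace or a [recording].
#' @param fs sampling rate (Hz).
#' @param stim_time_s stimulus onset (s).
#' @param artifact_ms artifact exclusion window after the stimulus.
#' @param fepsp_window_ms window for the initial field response (ms
#'   post-stimulus).
#' @param delayed_window_ms window for the delayed negative peak.
#' @param baseline_ms pre-stimulus baseline length.
#' @param noise_k flat-trace flag factor: deflections must exceed
#'   `noise_k` times the expected extremum of baseline noise over the
#'   analysis windows (`sd * sqrt(2 log n)`).
#' @param channel channel when `x` is a recording.
#' @return one-row tibble: `fepsp_amp`, `ps_amp`, `delayed_latency_ms`,
#'   `flagged`.
#' @export
evoked_metrics <- function(x, fs = NULL, stim_time_s, artifact_ms = 3,
                           fepsp_window_ms = c(3, 30),
                           delayed_window_ms = c(30, 300),
                           baseline_ms = 50, noise_k = 1.5, channel = 1L) {
  s <- resolve_signal(x, fs, channel)
  x <- s$x; fs <- s$fs
  st <- round(stim_time_s * fs) + 1L
  b0 <- max(1L, st - round(baseline_ms / 1000 * fs))
  base <- mean(x[b0:max(1L, st - 1L)])
  base_sd <- sd(x[b0:max(1L, st - 1L)])
  win_idx <- function(w_ms) {
    i0 <- st + round(max(w_ms[1], artifact_ms) / 1000 * fs)
    i1 <- min(length(x), st + round(w_ms[2] / 1000 * fs))
    i0:i1
  }
  fi <- win_idx(fepsp_window_ms)
  di <- win_idx(delayed_window_ms)
  seg_f <- x[fi]
  fepsp <- base - min(seg_f)
  ps <- max(seg_f) - min(seg_f)
  trough <- di[which.min(x[di])]
  latency <- (trough - st) * 1000 / fs
  flagged <- FALSE
  # expected extremum of pure baseline noise over the analysis windows
  n_win <- length(fi) + length(di)
  noise_floor <- max(base_sd, 1e-12) * sqrt(2 * log(max(n_win, 2)))
  if (max(abs(x[c(fi, di)] - base)) <= noise_k * noise_floor) {
    fepsp <- 0; ps <- 0; latency <- NA_real_; flagged <- TRUE
  }
  tibble(
    fepsp_amp = fepsp, ps_amp = ps, delayed_latency_ms = latency,
    flagged = flagged
  )
}

#' Score detected PSC events against generator ground truth
#'
#' Greedy one-to-one matching of detected threshold crossings to true
#' event times within `tol_ms`.
#'
#' @param detected tibble from [detect_psc_events()].
#' @param truth_times true event times (s).
#' @param tol_ms matching tolerance (ms).
#' @return one-row tibble: `recall`, `precision`, `n_true`, `n_detected`,
#'   `matched` (list-column of matched index pairs).
#' @export
score_psc_events <- function(detected, truth_times, tol_ms = 10) {
  tol <- tol_ms / 1000
  used <- rep(FALSE, nrow(detected))
  pairs <- list()
  hits <- 0L
  for (i in seq_along(truth_times)) {
    d <- abs(detected$time_s - truth_times[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      hits <- hits + 1L
      pairs[[length(pairs) + 1L]] <- c(truth = i, detected = j)
    }
  }
  tibble(
    recall = if (length(truth_times)) hits / length(truth_times) else NA_real_,
    precision = if (nrow(detected)) hits / nrow(detected) else NA_real_,
    n_true = length(truth_times), n_detected = nrow(detected),
    matched = list(do.call(rbind, pairs))
  )
}
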