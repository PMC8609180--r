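#' Morlet-wavelet time-frequency decomposition
#'
#' Convolution of the signal with scaled complex Morlet wavelets
#' (`cmor`-style, bandwidth `B`, center frequency `C`); the scale for each
#' target frequency f is `C / f` seconds per unit, so the wavelet's center
#' frequency equals f.  Each wavelet carries the `(pi B)^(-1/2)` Gaussian
#' prefactor and the discrete kernel is normalized so a unit complex
#' exponential at f yields unit-magnitude coefficients; for a real
#' sinusoid of amplitude A, `Mod(coeffs)` is approximately A/2.  The
#' magnitude of the coefficients is the instantaneous amplitude and their
#' argument the instantaneous phase.
#'
#' @param x numeric samples or a [recording].
#' @param fs sampling rate in Hz.
#' @param freqs analysis frequencies (Hz), strictly increasing, below
#'   Nyquist.
#' @param bandwidth wavelet bandwidth parameter B.
#' @param center wavelet center frequency parameter C.
#' @param channel channel when `x` is a recording.
#' @return object of class `tf_map`: `freqs_Hz`, `times_s`, `coeffs`
#'   (complex matrix, frequency x time), `fs`.
#' @export
morlet_tf <- function(x, fs = NULL, freqs, bandwidth = 5, center = 0.8125,
                      channel = 1L) {
  s <- resolve_signal(x, fs, channel)
  x <- s$x; fs <- s$fs
  freqs <- as.numeric(freqs)
  if (any(freqs <= 0) || any(freqs >= fs / 2)) {
    abort("invalid frequency: freqs must lie in (0, fs/2)")
  }
  if (is.unsorted(freqs, strictly = TRUE)) abort("freqs must be strictly increasing")
  n <- length(x)
  coeffs <- matrix(0i, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    coeffs[k, ] <- morlet_conv(x, fs, freqs[k], bandwidth, center)
  }
  structure(
    list(freqs_Hz = freqs, times_s = (seq_len(n) - 1) / fs,
      coeffs = coeffs, fs = fs),
    class = "tf_map"
  )
}

# Single-frequency complex Morlet convolution ("same" alignment).
morlet_conv <- function(x, fs, f, bandwidth, center) {
  a <- center / f                      # scale, seconds
  sigma_t <- a * sqrt(bandwidth / 2)   # envelope SD, seconds
  half <- ceiling(4 * sigma_t * fs)
  tk <- seq(-half, half) / fs
  u <- tk / a
  w <- (pi * bandwidth)^(-0.5) * exp(-u^2 / bandwidth) *
    exp(2i * pi * center * u)
  w <- w / (a * fs) # unit gain at the center frequency
  n <- length(x)
  m <- length(w)
  y <- fft_conv(c(x, rep(0, m - 1L)), Conj(rev(w)))
  y[seq(m, m + n - 1L)]
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf(
    "<tf_map> %d frequencies (%g-%g Hz) x %d time points @ %g Hz\n",
    length(x$freqs_Hz), min(x$freqs_Hz), max(x$freqs_Hz),
    ncol(x$coeffs), x$fs
  ))
  invisible(x)
}

#' @export
as_tibble.tf_map <- function(x, ...) {
  tidyr::expand_grid(freq_Hz = x$freqs_Hz, time_s = x$times_s) |>
    dplyr::mutate(power = as.vector(t(Mod(x$coeffs)^2)))
}

#' Z-score a time-frequency map to a quiescent baseline
#'
#' Per frequency, power is standardized to the mean and SD of a baseline
#' window: `z = (power - mu_baseline) / sd_baseline`.
#'
#' @param tf a `tf_map` from [morlet_tf()].
#' @param baseline numeric length-2, `(t0, t1)` seconds, at least 1 s long
#'   and within the map's time range.
#' @return a `tf_map` whose `coeffs` field is replaced by a real `z` matrix
#'   (class `tf_zmap`).
#' @export
zscore_to_baseline <- function(tf, baseline) {
  stopifnot(inherits(tf, "tf_map"))
  if (baseline[2] - baseline[1] < 1) abort("baseline must be at least 1 s")
  sel <- tf$times_s >= baseline[1] & tf$times_s < baseline[2]
  if (!any(sel) || baseline[1] < min(tf$times_s) ||
    baseline[2] > max(tf$times_s) + 1 / tf$fs) {
    abort("baseline outside the map's time range")
  }
  pow <- Mod(tf$coeffs)^2
  mu <- rowMeans(pow[, sel, drop = FALSE])
  sdv <- apply(pow[, sel, drop = FALSE], 1, sd)
  z <- (pow - mu) / sdv
  degenerate <- sdv == 0
  if (any(degenerate)) {
    warn("zero baseline variance at some frequencies; rows set to NaN")
    z[degenerate, ] <- NaN
  }
  structure(
    list(freqs_Hz = tf$freqs_Hz, times_s = tf$times_s, z = z, fs = tf$fs),
    class = "tf_zmap"
  )
}

#' Phase-amplitude modulation index (normalized KL distance)
#'
#' The phase series is divided into `n_bins` equal intervals (20 degrees
#' each by default, left-closed on \[-180, 180)); the amplitude is averaged
#' within each bin and normalized to sum to one; the index is the
#' Kullback-Leibler distance of that distribution from uniform, divided by
#' `log(n_bins)` so it lies in \[0, 1\].  Zero means the amplitude is
#' independent of phase; one means all amplitude mass concentrates in a
#' single bin.
#'
#' @param phase numeric vector of phases in radians.
#' @param amp positive numeric vector, same length.
#' @param n_bins number of phase bins.
#' @return list: `mi` (scalar), `binned` (tibble with `bin_lo_deg`,
#'   `bin_hi_deg`, `a_high`, `a_norm`).
#' @export
modulation_index <- function(phase, amp, n_bins = 18) {
  if (length(phase) != length(amp)) abort("phase and amp must have equal length")
  if (any(amp < 0)) abort("domain error: amplitudes must be nonnegative")
  if (all(amp == 0)) abort("domain error: amplitudes are all zero")
  b <- phase_bins(phase, n_bins)
  cnt <- tabulate(b, nbins = n_bins)
  if (any(cnt == 0)) abort("insufficient phase coverage: empty phase bin")
  a_high <- as.vector(rowsum(amp, b)) / cnt
  a_norm <- a_high / sum(a_high)
  mi <- kl_mi(a_norm, n_bins)
  edges <- seq(-180, 180, length.out = n_bins + 1)
  list(
    mi = mi,
    binned = tibble(
      bin_lo_deg = edges[-(n_bins + 1)], bin_hi_deg = edges[-1],
      a_high = a_high, a_norm = a_norm
    )
  )
}

# Bin phases (radians) into n left-closed bins on [-pi, pi).
phase_bins <- function(phase, n_bins) {
  p <- (phase + pi) %% (2 * pi)
  b <- floor(p / (2 * pi / n_bins)) + 1L
  pmin.int(b, n_bins)
}

# Normalized KL distance of a probability vector from uniform (natural log).
kl_mi <- function(p, n_bins) {
  nz <- p > 0
  sum(p[nz] * log(p[nz] * n_bins)) / log(n_bins)
}

#' Comodulogram: modulation index over a phase x amplitude frequency grid
#'
#' The index is estimated on a window (default 10 s) centered on a burst
#' midpoint.  Wavelet coefficients are computed on the window extended by
#' `pad_s` on either side, and the pad is trimmed before the index is
#' formed, so filter edge effects do not contaminate the estimate.  Phase
#' comes from the low-frequency wavelet coefficients, amplitude from the
#' high-frequency ones.
#'
#' @param x numeric samples or a [recording].
#' @param fs sampling rate (Hz).
#' @param center_s window center (s), typically a burst midpoint.
#' @param window_s analysis window length (s).
#' @param pad_s edge pad on each side (s).
#' @param phase_freqs phase (slow) frequencies, Hz.
#' @param amp_freqs amplitude (fast) frequencies, Hz.
#' @param n_bins phase bins.
#' @param bandwidth,center Morlet parameters, see [morlet_tf()].
#' @param channel channel when `x` is a recording.
#' @return object of class `pac_result`: `mi` (phase x amp matrix),
#'   `phase_freqs_Hz`, `amp_freqs_Hz`, `peak_pair`, plus the internal
#'   binned phase/amplitude series reused by [surrogate_significance()].
#' @examples
#' sim <- gen_coupled_lfp(coupled_lfp_spec(
#'   duration_s = 30, burst_times_s = 14, burst_dur_s = 2, seed = 2
#' ))
#' pac <- comodulogram(sim$recording, center_s = 15)
#' pac$peak_pair
#' @export
comodulogram <- function(x, fs = NULL, center_s, window_s = 10, pad_s = 5,
                         phase_freqs = seq(1, 12, by = 0.5),
                         amp_freqs = seq(30, 250, by = 5),
                         n_bins = 18, bandwidth = 5, center = 0.8125,
                         channel = 1L) {
  s <- resolve_signal(x, fs, channel)
  x <- s$x; fs <- s$fs
  half <- window_s / 2 + pad_s
  i0 <- round((center_s - half) * fs) + 1L
  i1 <- round((center_s + half) * fs)
  if (i0 < 1L || i1 > length(x)) abort("window out of range")
  if (max(amp_freqs) >= fs / 2) {
    abort("invalid frequency: amplitude band exceeds Nyquist; decimation must be skipped for HFO analysis above 250 Hz unless fs is sufficient")
  }
  seg <- x[i0:i1]
  trim <- seq(round(pad_s * fs) + 1L, length(seg) - round(pad_s * fs))
  tf_lo <- morlet_tf(seg, fs, phase_freqs, bandwidth, center)
  tf_hi <- morlet_tf(seg, fs, amp_freqs, bandwidth, center)
  phase <- Arg(tf_lo$coeffs[, trim, drop = FALSE])
  amp <- Mod(tf_hi$coeffs[, trim, drop = FALSE])
  bins <- matrix(0L, nrow = length(phase_freqs), ncol = length(trim))
  for (k in seq_along(phase_freqs)) bins[k, ] <- phase_bins(phase[k, ], n_bins)
  mi <- mi_grid(bins, amp, n_bins)
  dimnames(mi) <- list(phase_freqs, amp_freqs)
  pk <- arrayInd(which.max(mi), dim(mi))
  structure(
    list(
      mi = mi, phase_freqs_Hz = phase_freqs, amp_freqs_Hz = amp_freqs,
      peak_pair = c(phase_Hz = phase_freqs[pk[1]], amp_Hz = amp_freqs[pk[2]]),
      n_bins = n_bins, fs = fs, window_s = window_s, pad_s = pad_s,
      center_s = center_s, bins = bins, amp = amp,
      mean_power = mean(amp^2)
    ),
    class = "pac_result"
  )
}

# MI for every (phase row of `bins`) x (amplitude row of `amp`) pair.
# bins: n_phase x n_t integer matrix; amp: n_amp x n_t nonnegative matrix.
mi_grid <- function(bins, amp, n_bins) {
  n_phase <- nrow(bins)
  n_amp <- nrow(amp)
  at <- t(amp) # n_t x n_amp: rowsum() groups time samples by phase bin
  mi <- matrix(NA_real_, n_phase, n_amp)
  logn <- log(n_bins)
  for (k in seq_len(n_phase)) {
    b <- bins[k, ]
    cnt <- tabulate(b, nbins = n_bins)
    sums <- rowsum(at, b) # n_bins x n_amp (all bins occupied on dense input)
    means <- sums / cnt
    p <- sweep(means, 2, colSums(means), "/")
    mi[k, ] <- colSums(ifelse(p > 0, p * log(p * n_bins), 0)) / logn
  }
  mi
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf(
    "<pac_result> %d x %d grid; peak MI %.4f at (%.1f Hz phase, %.0f Hz amplitude)\n",
    nrow(x$mi), ncol(x$mi), max(x$mi), x$peak_pair[1], x$peak_pair[2]
  ))
  if (!is.null(x$z)) {
    cat(sprintf("  surrogate z at peak %.2f; %d significant cell(s) (z > 3)\n",
      x$z[which.max(x$mi)], sum(x$sig_mask, na.rm = TRUE)))
  }
  invisible(x)
}

#' Block-shuffle surrogate significance for a comodulogram
#'
#' For each surrogate the phase series is partitioned into consecutive
#' blocks and the blocks are permuted at random; the amplitude series is
#' untouched and the modulation index is recomputed on the shuffled
#' pairing.  The observed index is then z-scored against the surrogate
#' distribution per grid cell; cells with z > 3 form the significance
#' mask.
#'
#' Block lengths are drawn uniformly between `block_frac[1]` and
#' `block_frac[2]` seconds per block (re-drawn for every surrogate).  The
#' default 0.25--0.75 s serves two constraints at once: blocks must be
#' longer than the amplitude autocorrelation time, or the surrogate null
#' is too narrow and the false-positive rate explodes; and block lengths
#' must not be a fixed multiple of a carrier period, or the shuffle
#' preserves phase alignment and the test loses all power at that phase
#' frequency.  Passing a scalar `block_frac` gives fixed-length blocks of
#' `round(block_frac * fs)` samples (0.01, i.e. 1% of the sampling rate,
#' reproduces the reference analysis; see the methods vignette for why
#' that null is anticonservative on autocorrelated amplitude series).
#'
#' @param pac a `pac_result` from [comodulogram()].
#' @param n_surrogates number of surrogate shuffles.
#' @param block_frac block length in seconds (scalar: fixed; length 2:
#'   random uniform range per block).
#' @param seed optional RNG seed for the shuffles.
#' @return the `pac_result` with `z` (matrix), `sig_mask` (logical matrix),
#'   and `surrogate_mean`/`surrogate_sd` matrices added.  Cells with zero
#'   surrogate SD get `z = Inf` and are excluded from the mask with a
#'   warning.
#' @export
surrogate_significance <- function(pac, n_surrogates = 100,
                                   block_frac = c(0.25, 0.75),
                                   seed = NULL) {
  stopifnot(inherits(pac, "pac_result"))
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  n_t <- ncol(pac$bins)
  sum_mi <- matrix(0, nrow(pac$mi), ncol(pac$mi))
  sum_mi2 <- sum_mi
  for (s in seq_len(n_surrogates)) {
    idx <- shuffle_blocks(n_t, block_frac, pac$fs)
    mi_s <- mi_grid(pac$bins[, idx, drop = FALSE], pac$amp, pac$n_bins)
    sum_mi <- sum_mi + mi_s
    sum_mi2 <- sum_mi2 + mi_s^2
  }
  mu <- sum_mi / n_surrogates
  sdv <- sqrt(pmax(0, sum_mi2 / n_surrogates - mu^2) *
    n_surrogates / (n_surrogates - 1))
  z <- (pac$mi - mu) / sdv
  if (any(sdv == 0)) {
    warn("zero surrogate SD at some cells; z set to Inf and excluded from the mask")
    z[sdv == 0] <- Inf
  }
  pac$z <- z
  pac$sig_mask <- is.finite(z) & z > 3
  pac$surrogate_mean <- mu
  pac$surrogate_sd <- sdv
  pac
}

# One block-shuffled index vector of 1..n_t.  Scalar block_frac: fixed
# blocks of round(block_frac * fs) samples; length-2: lengths drawn
# uniformly in [block_frac[1], block_frac[2]] seconds.
shuffle_blocks <- function(n_t, block_frac, fs) {
  if (length(block_frac) == 1L) {
    block_len <- max(1L, round(block_frac * fs))
    n_blocks <- ceiling(n_t / block_len)
    lens <- rep(block_len, n_blocks)
    lens[n_blocks] <- n_t - (n_blocks - 1L) * block_len
  } else {
    lens <- integer(0)
    while (sum(lens) < n_t) {
      lens <- c(lens, pmax(1L, round(runif(16, block_frac[1], block_frac[2]) * fs)))
    }
    extra <- sum(lens) - n_t
    while (extra > 0) {
      k <- length(lens)
      if (lens[k] > extra) {
        lens[k] <- lens[k] - extra
        extra <- 0L
      } else {
        extra <- extra - lens[k]
        lens <- lens[-k]
      }
    }
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  perm <- sample.int(length(lens))
  unlist(lapply(perm, function(bk) starts[bk]:ends[bk]), use.names = FALSE)
}

# Recompute the observed MI grid under an explicit block permutation; the
# identity permutation must reproduce the original grid exactly.
apply_phase_permutation <- function(pac, perm, block_frac = 0.01) {
  block_len <- max(1L, round(block_frac * pac$fs))
  n_t <- ncol(pac$bins)
  n_blocks <- ceiling(n_t / block_len)
  stopifnot(length(perm) == n_blocks)
  block_start <- (seq_len(n_blocks) - 1L) * block_len + 1L
  block_end <- pmin(n_t, block_start + block_len - 1L)
  idx <- unlist(lapply(perm, function(bk) block_start[bk]:block_end[bk]),
    use.names = FALSE)
  mi_grid(pac$bins[, idx, drop = FALSE], pac$amp, pac$n_bins)
}

#' Power vs modulation-index control for PAC validity
#'
#' Apparent coupling driven by broadband power fluctuations shows a
#' positive relation between wavelet power and the maximal modulation index
#' across bursts; true PAC does not.  The verdict is "consistent with true
#' PAC" when the correlation is negative or not significantly positive.
#'
#' @param power_values wavelet power per burst.
#' @param mi_values maximal modulation index per burst, same length >= 3.
#' @param alpha significance level for the positive-correlation test.
#' @return one-row tibble: `rho`, `p`, `slope_sign`, `verdict`.
#' @export
mi_power_control <- function(power_values, mi_values, alpha = 0.05) {
  if (length(power_values) != length(mi_values) || length(mi_values) < 3) {
    abort("need equal-length inputs with at least 3 bursts")
  }
  if (sd(power_values) == 0 || sd(mi_values) == 0) {
    abort("undefined correlation: constant input")
  }
  ct <- cor.test(power_values, mi_values, method = "pearson")
  slope <- coef(lm(mi_values ~ power_values))[2]
  positive <- ct$estimate > 0 && ct$p.value < alpha
  tibble(
    rho = unname(ct$estimate), p = ct$p.value,
    slope_sign = sign(unname(slope)),
    verdict = if (!positive) "consistent with true PAC" else
      "power-driven coupling suspected"
  )
}
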