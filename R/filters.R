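#' Signal conditioning: zero-phase FIR filtering, decimation, envelopes
#'
#' These routines implement the filtering conventions used throughout the
#' pipeline: linear-phase FIR designs applied forward and reverse so the net
#' phase response is zero and event timing is undistorted.
#'
#' @name filters
NULL

# Full linear convolution via FFT.  Handles complex kernels.
fft_conv <- function(x, h) {
  n_out <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n_out, 2)
  y <- fft(fft(c(x, rep(0, nfft - length(x)))) *
    fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE) / nfft
  y[seq_len(n_out)]
}

# Analytic signal via the one-sided spectrum construction: zero out negative
# frequencies, double positive ones.  Mod() of the result is the envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Cap an FIR order so forward-reverse filtering has enough signal to work
# with; mirrors the auto-reduction the user-facing filters document.
cap_filter_order <- function(order, n, quiet = FALSE) {
  max_order <- floor(n / 3) - 1L
  if (max_order < 8L) abort("signal too short to filter")
  if (order > max_order) {
    if (!quiet) {
      inform(sprintf(
        "filter order reduced from %d to %d for a %d-sample signal",
        order, max_order, n
      ))
    }
    order <- max_order
  }
  # even order -> odd-length symmetric (type I) FIR, valid for band-pass
  if (order %% 2L == 1L) order <- order - 1L
  order
}

# Apply an FIR `b` forward and reverse (zero net phase) with odd-symmetric
# edge reflection.  Equivalent to one pass with conv(b, rev(b)), which is
# symmetric, so the group delay is known exactly and removed.
fir_zerophase <- function(x, b) {
  n <- length(x)
  m <- length(b)
  g <- fft_conv(b, rev(b)) # zero-phase composite kernel, length 2m-1
  pad <- min(n - 1L, m - 1L)
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  y <- Re(fft_conv(xp, g))
  y[seq(pad + m, pad + m + n - 1L)]
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR band-pass applied forward and reverse, so the output
#' has zero net phase shift and the same length as the input.  The default
#' order (10000) suits multi-minute LFP traces; it is automatically reduced
#' (with a message) to `floor(n/3) - 1` on shorter signals.
#'
#' @param x numeric vector of samples, or a [recording].
#' @param fs sampling rate in Hz (ignored when `x` is a recording).
#' @param band numeric length-2, `(lo, hi)` band edges in Hz; must lie
#'   strictly inside (0, fs/2).
#' @param order FIR filter order.
#' @param channel channel to use when `x` is a recording.
#' @return numeric vector of filtered samples, same length as the input.
#' @examples
#' fs <- 1000
#' t <- seq(0, 10, by = 1 / fs)
#' y <- zero_phase_bandpass(sin(2 * pi * 5 * t), fs, c(4, 6))
#' @export
zero_phase_bandpass <- function(x, fs = NULL, band, order = 10000, channel = 1L) {
  s <- resolve_signal(x, fs, channel)
  x <- s$x; fs <- s$fs
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
    band[2] >= fs / 2) {
    abort("invalid band: need 0 < lo < hi < fs/2")
  }
  if (any(!is.finite(x))) abort("non-finite samples")
  order <- cap_filter_order(order, length(x))
  b <- fir_bandpass(order, band, fs)
  fir_zerophase(x, b)
}

# Hamming-window band-pass design, normalized to unit gain at the band
# center (fir1's own rescaling returns NaN for very narrow normalized
# bands, so the normalization is done explicitly).
fir_bandpass <- function(order, band, fs) {
  b <- signal::fir1(order, band / (fs / 2), type = "pass", scale = FALSE)
  f0 <- mean(band)
  g <- Mod(sum(b * exp(-2i * pi * f0 / fs * seq(0, order))))
  if (!is.finite(g) || g < 1e-6) {
    abort("filter design degenerate: order too low for this band; increase `order`")
  }
  b / g
}

#' Decimate a signal to a lower sampling rate
#'
#' Anti-alias low-pass (zero-phase FIR, cutoff at 0.475 of the target rate)
#' followed by downsampling.  Passband amplitudes are preserved to within
#' 1%.  Non-integer rate ratios are handled by polyphase resampling with a
#' warning.
#'
#' @inheritParams zero_phase_bandpass
#' @param target_fs desired sampling rate in Hz, at most `fs`.
#' @param order anti-aliasing FIR order.
#' @return For vector input, a numeric vector at `target_fs`; for a
#'   [recording], a recording with all channels decimated.
#' @export
decimate_to <- function(x, fs = NULL, target_fs = 1000, order = 400,
                        channel = NULL) {
  if (inherits(x, "recording")) {
    if (!is.null(channel)) {
      return(decimate_to(get_channel(x, channel), x$fs, target_fs, order))
    }
    dec <- lapply(seq_len(n_channels(x)), function(i) {
      decimate_to(x$data[i, ], x$fs, target_fs, order)
    })
    return(recording(do.call(rbind, dec), target_fs,
      units = x$units, channel_labels = x$channel_labels, t0 = x$t0
    ))
  }
  if (fs < target_fs) abort("cannot upsample")
  if (fs == target_fs) return(as.numeric(x))
  q <- fs / target_fs
  order <- cap_filter_order(order, length(x), quiet = TRUE)
  b <- signal::fir1(order, (0.475 * target_fs) / (fs / 2))
  y <- fir_zerophase(as.numeric(x), b)
  if (abs(q - round(q)) < 1e-9) {
    y[seq(1L, length(y), by = round(q))]
  } else {
    warn(sprintf("fs/target_fs = %.3f is not an integer; resampling", q))
    ti <- seq(0, (length(y) - 1) / fs, by = 1 / target_fs)
    approx(seq(0, by = 1 / fs, length.out = length(y)), y, xout = ti)$y
  }
}

#' Band-pass filter for postsynaptic-current detection
#'
#' Kaiser-window FIR band-pass for voltage-clamp traces sampled at 1 kHz,
#' designed to the template: stopband below 5 Hz (60 dB), passband
#' 15--150 Hz (1 dB ripple), stopband above 200 Hz (40 dB); applied
#' zero-phase (forward and reverse), which deepens the realized stopbands.
#'
#' @param x numeric vector of current samples (pA) at 1 kHz, or a
#'   [recording] at 1 kHz.
#' @param fs sampling rate; must be 1000 Hz -- decimate first with
#'   [decimate_to()].
#' @param channel channel to use when `x` is a recording.
#' @return filtered numeric vector, same length as input.
#' @export
psc_bandpass <- function(x, fs = NULL, channel = 1L) {
  s <- resolve_signal(x, fs, channel)
  if (abs(s$fs - 1000) > 1e-6) abort("decimate first: psc_bandpass expects fs = 1000 Hz")
  b <- psc_filter_coefficients()
  fir_zerophase(s$x, b)
}

# Kaiser-window design for the PSC band-pass template; cached per session.
psc_filter_coefficients <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dev <- c(10^(-60 / 20), (10^(1 / 20) - 1) / (10^(1 / 20) + 1), 10^(-40 / 20))
    ko <- signal::kaiserord(c(5, 15, 150, 200), c(0, 1, 0), dev, 1000)
    n <- ko$n
    if (n %% 2L == 1L) n <- n + 1L
    cache <<- signal::fir1(n, ko$Wc, type = "pass",
      window = signal::kaiser(n + 1, ko$beta), scale = FALSE)
    cache
  }
})

#' Smoothed power envelope of a band-limited signal
#'
#' Squares the input, convolves with a unit-sum Gaussian kernel
#' (`aperture`-sample window, sigma = aperture/6), and takes the upper
#' envelope of the smoothed power.  The default envelope interpolates
#' linearly through the local maxima of the smoothed power (which ripples
#' at twice the carrier frequency); `method = "analytic"` uses the
#' magnitude of the analytic signal instead.  The peak envelope is the
#' default because the Hilbert transform of a nonnegative power bump has
#' slowly decaying tails that smear threshold crossings by hundreds of
#' milliseconds, destroying onset accuracy; see the methods vignette.
#' This is the detection trace used by [detect_bursts()].
#'
#' @param x numeric vector (typically already band-passed).
#' @param kernel_aperture Gaussian kernel window length in samples.
#' @param method `"peak"` (interpolated local maxima) or `"analytic"`.
#' @return numeric vector: nonnegative envelope, same length as `x`.
#' @export
power_envelope <- function(x, kernel_aperture = 200,
                           method = c("peak", "analytic")) {
  method <- match.arg(method)
  p <- x^2
  k <- gaussian_kernel(kernel_aperture)
  sm <- conv_same(p, k)
  if (method == "analytic") return(Mod(analytic_signal(sm)))
  n <- length(sm)
  core <- sm[2:(n - 1)]
  pk <- which(core >= sm[1:(n - 2)] & core >= sm[3:n]) + 1L
  knots <- unique(c(1L, pk, n))
  approx(knots, sm[knots], xout = seq_len(n))$y
}

gaussian_kernel <- function(aperture) {
  stopifnot(aperture >= 3)
  half <- (aperture - 1) / 2
  u <- seq(-half, half, length.out = aperture)
  k <- exp(-u^2 / (2 * (aperture / 6)^2))
  k / sum(k)
}

# Centered ("same") convolution with edge replication.
conv_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  pad <- m - 1L
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  y <- Re(fft_conv(xp, k))
  shift <- floor((m - 1) / 2)
  y[seq(pad + 1L + shift, pad + shift + n)]
}
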