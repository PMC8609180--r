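# Independent oracles used across tests.

# Brute-force normalized-KL modulation index: direct binning and explicit
# KL series, independent of the package's vectorized implementation.
mi_bruteforce <- function(phase, amp, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  p <- (phase + pi) %% (2 * pi) - pi
  m <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    sel <- p >= edges[j] & p < edges[j + 1]
    m[j] <- mean(amp[sel])
  }
  pr <- m / sum(m)
  kl <- 0
  for (j in seq_len(n_bins)) {
    if (pr[j] > 0) kl <- kl + pr[j] * log(pr[j] / (1 / n_bins))
  }
  kl / log(n_bins)
}

# Frequency-domain ideal band-pass (hard spectral mask): oracle for what a
# good band-pass should keep.
fft_mask_bandpass <- function(x, fs, band) {
  n <- length(x)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) * fs / n
  keep <- f >= band[1] & f <= band[2]
  Re(fft(fft(x) * keep, inverse = TRUE) / n)
}

# A small coupled-LFP fixture shared by several tests.
quick_coupled_fixture <- function(seed = 2, depth = 0.8) {
  gen_coupled_lfp(coupled_lfp_spec(
    duration_s = 25, burst_times_s = 7.5, burst_dur_s = 10,
    coupling_depth = depth, seed = seed
  ))
}
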