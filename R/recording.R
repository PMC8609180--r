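#' Multichannel sampled recording
#'
#' A `recording` is the package's container for sampled electrophysiology
#' signals: a channels-by-time numeric matrix plus the sampling rate and
#' per-channel metadata.  It holds extracellular LFP (uV), voltage-clamp
#' current (pA) or current-clamp voltage (mV) traces interchangeably.
#'
#' @param data numeric matrix, channels x time, or a numeric vector for a
#'   single channel.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param units character vector of per-channel unit strings (e.g. `"uV"`,
#'   `"pA"`, `"mV"`); recycled if length 1.
#' @param channel_labels character vector of channel names; defaults to
#'   `ch1, ch2, ...`.
#' @param t0 start time of the first sample in seconds.
#'
#' @return An object of class `recording` with fields `data`, `fs`, `units`,
#'   `channel_labels`, `t0`.
#' @examples
#' rec <- recording(matrix(rnorm(2000), nrow = 2), fs = 1000, units = "uV")
#' rec
#' @export
recording <- function(data, fs, units = "uV", channel_labels = NULL, t0 = 0) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels-by-time matrix.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  nch <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nch))
  if (length(units) == 1L) units <- rep(units, nch)
  if (length(units) != nch) {
    abort("`units` must have one entry per channel.")
  }
  if (length(channel_labels) != nch) {
    abort("`channel_labels` must have one entry per channel.")
  }
  structure(
    list(
      data = data, fs = as.numeric(fs), units = as.character(units),
      channel_labels = as.character(channel_labels), t0 = as.numeric(t0)
    ),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channel(s) x %d samples @ %g Hz (%.3f s), t0 = %g s\n",
    n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs, x$t0
  ))
  cat("  channels:", paste(sprintf("%s [%s]", x$channel_labels, x$units),
    collapse = ", "), "\n")
  invisible(x)
}

#' @rdname recording
#' @param x a `recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname recording
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname recording
#' @export
rec_duration <- function(x) n_samples(x) / x$fs

#' Sample times of a recording
#' @param x a `recording`.
#' @return numeric vector of times in seconds (0-based sample convention,
#'   offset by `t0`).
#' @export
rec_times <- function(x) x$t0 + (seq_len(n_samples(x)) - 1) / x$fs

#' Extract one channel of a recording as a numeric vector
#'
#' @param x a `recording`.
#' @param channel channel index or label.
#' @return numeric vector of samples.
#' @export
get_channel <- function(x, channel = 1L) {
  stopifnot(inherits(x, "recording"))
  if (is.character(channel)) {
    idx <- match(channel, x$channel_labels)
    if (is.na(idx)) abort(sprintf("unknown channel label '%s'", channel))
  } else {
    idx <- as.integer(channel)
    if (idx < 1L || idx > n_channels(x)) abort("channel index out of range")
  }
  x$data[idx, ]
}

#' @export
as_tibble.recording <- function(x, ...) {
  out <- tibble(time_s = rec_times(x))
  for (i in seq_len(n_channels(x))) out[[x$channel_labels[i]]] <- x$data[i, ]
  out
}

# Resolve a (signal, fs) pair from either a recording + channel or a bare
# numeric vector + fs.  Most analysis entry points accept both.
resolve_signal <- function(x, fs = NULL, channel = 1L) {
  if (inherits(x, "recording")) {
    list(x = get_channel(x, channel), fs = x$fs)
  } else {
    if (is.null(fs)) abort("`fs` is required when `x` is a bare numeric vector.")
    list(x = as.numeric(x), fs = fs)
  }
}
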