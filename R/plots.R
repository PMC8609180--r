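#' Plot a comodulogram
#'
#' Heatmap of the modulation index over the phase x amplitude frequency
#' grid; significant cells (surrogate z > 3), when available, are outlined.
#'
#' @param object a `pac_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pac_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$phase_Hz, .data$amp_Hz)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$mi)) +
    ggplot2::scale_fill_viridis_c(name = "MI") +
    ggplot2::labs(
      x = "phase frequency (Hz)", y = "amplitude frequency (Hz)",
      title = "Phase-amplitude coupling comodulogram"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(df$significant) && any(df$significant)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(df, .data$significant),
      shape = 0, size = 1, colour = "white"
    )
  }
  p
}

#' Plot detected bursts over the raw trace
#'
#' @param rec a [recording].
#' @param events tibble from [detect_bursts()].
#' @param channel channel to draw.
#' @return a ggplot object.
#' @export
plot_bursts <- function(rec, events, channel = 1L) {
  df <- tibble(time_s = rec_times(rec), v = get_channel(rec, channel))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$v)) +
    ggplot2::geom_rect(
      data = events, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
        ymin = -Inf, ymax = Inf),
      fill = "tomato", alpha = 0.2
    ) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = sprintf("signal (%s)",
      rec$units[channel])) +
    ggplot2::theme_minimal()
}

#' Plot an F-I curve with its shifted fit
#'
#' @param object an `fi_fit` from [fi_analysis()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fi_fit <- function(object, ...) {
  df <- object$fi
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$current_pA, .data$rate_Hz)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "injected current (pA)", y = "firing rate (Hz)") +
    ggplot2::theme_minimal()
  if (!object$flagged) {
    p <- p + ggplot2::geom_vline(xintercept = object$rheobase_pA,
      linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot an empirical CDF
#'
#' @param object an `ecdf_table` from [ecdf_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ecdf_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$prob)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "value", y = "cumulative probability") +
    ggplot2::theme_minimal()
}
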