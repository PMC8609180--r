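#' Tidy a gamma fit
#' @param x a `gamma_fit` from [fit_gamma()].
#' @param ... unused.
#' @return tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble(
    term = c("shape", "scale"),
    estimate = c(x$shape_k, x$scale_theta),
    conf.low = c(x$shape_ci[1], NA_real_),
    conf.high = c(x$shape_ci[2], NA_real_)
  )
}

#' @rdname tidy.gamma_fit
#' @export
glance.gamma_fit <- function(x, ...) {
  tibble(shape = x$shape_k, scale = x$scale_theta, n = x$n, logLik = x$loglik)
}

#' Tidy a current-voltage fit
#' @param x an `iv_fit` from [reversal_potential()].
#' @param ... unused.
#' @return tibble of fitted terms.
#' @export
tidy.iv_fit <- function(x, ...) {
  tibble(
    term = c("slope", "intercept", "e_rev_mV"),
    estimate = c(x$slope, x$intercept, x$e_rev_mV)
  )
}

#' @rdname tidy.iv_fit
#' @export
glance.iv_fit <- function(x, ...) {
  tibble(
    e_rev_mV = x$e_rev_mV, slope = x$slope,
    spearman_rho = x$spearman_rho, p = x$p, n = nrow(x$points)
  )
}

#' Tidy a comodulogram into long format
#' @param x a `pac_result` from [comodulogram()].
#' @param ... unused.
#' @return tibble: `phase_Hz`, `amp_Hz`, `mi`, and (when surrogates were
#'   run) `z` and `significant`.
#' @export
tidy.pac_result <- function(x, ...) {
  out <- tidyr::expand_grid(
    phase_Hz = x$phase_freqs_Hz, amp_Hz = x$amp_freqs_Hz
  )
  out$mi <- as.vector(t(x$mi))
  if (!is.null(x$z)) {
    out$z <- as.vector(t(x$z))
    out$significant <- as.vector(t(x$sig_mask))
  }
  out
}

#' @rdname tidy.pac_result
#' @export
glance.pac_result <- function(x, ...) {
  tibble(
    peak_phase_Hz = unname(x$peak_pair[1]),
    peak_amp_Hz = unname(x$peak_pair[2]),
    peak_mi = max(x$mi),
    peak_z = if (!is.null(x$z)) x$z[which.max(x$mi)] else NA_real_,
    n_significant = if (!is.null(x$sig_mask)) sum(x$sig_mask, na.rm = TRUE)
      else NA_integer_
  )
}

#' Tidy an F-I fit
#' @param x an `fi_fit` from [fi_analysis()].
#' @param ... unused.
#' @return the F-I curve tibble.
#' @export
tidy.fi_fit <- function(x, ...) x$fi

#' @rdname tidy.fi_fit
#' @export
glance.fi_fit <- function(x, ...) {
  tibble(
    rheobase_pA = x$rheobase_pA, slope_Hz_per_pA = x$slope_Hz_per_pA,
    shift_origin_pA = x$shift_origin_pA, flagged = x$flagged
  )
}

#' Tidy extracted membrane properties
#' @param x a `membrane_props` object.
#' @param ... unused.
#' @return long tibble of `property`, `value`.
#' @export
tidy.membrane_props <- function(x, ...) {
  tidyr::pivot_longer(x$summary, dplyr::everything(),
    names_to = "property", values_to = "value")
}

#' @rdname tidy.membrane_props
#' @export
glance.membrane_props <- function(x, ...) x$summary
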