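#' Two-sample comparison (t, rank-sum, or Kolmogorov-Smirnov)
#'
#' Two-sided tests throughout.  The t test defaults to the equal-variance
#' unpaired form (set `welch = TRUE` for the unequal-variance variant); the
#' rank-sum test is exact for groups of 10 or fewer and uses the normal
#' approximation with continuity correction above that; the KS test uses
#' the two-sample sup-difference statistic.
#'
#' @param a,b numeric samples, each of length >= 3.
#' @param method `"t"`, `"ranksum"` or `"ks"`.
#' @param welch use the Welch t variant.
#' @return one-row tibble: `method`, `statistic`, `p`, `n1`, `n2`.
#' @export
compare_two <- function(a, b, method = c("t", "ranksum", "ks"),
                        welch = FALSE) {
  method <- match.arg(method)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 3 || n2 < 3) abort("need at least 3 observations per group")
  res <- switch(method,
    t = {
      if (sd(a) == 0 && sd(b) == 0 && a[1] == b[1]) {
        list(statistic = 0, p.value = 1)
      } else {
        ht <- t.test(a, b, var.equal = !welch)
        list(statistic = unname(ht$statistic), p.value = ht$p.value)
      }
    },
    ranksum = {
      ht <- suppressWarnings(wilcox.test(a, b,
        exact = (n1 <= 10 && n2 <= 10), correct = TRUE
      ))
      list(statistic = unname(ht$statistic), p.value = ht$p.value)
    },
    ks = {
      ht <- suppressWarnings(ks.test(a, b))
      list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
  )
  tibble(method = method, statistic = res$statistic, p = res$p.value,
    n1 = n1, n2 = n2)
}

#' Bonferroni correction
#'
#' `adjusted = min(1, p * m)`, with `m` defaulting to the number of tests.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @param m number of comparisons.
#' @return adjusted p values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1)) abort("invalid p: outside [0, 1]")
  p.adjust(p_values, method = "bonferroni", n = max(m, length(p_values)))
}

#' Correlation with the standard strength banding
#'
#' Spearman or Pearson correlation with a two-sided p value.  For Pearson,
#' the absolute coefficient is labeled by the conventional bands: 0 no
#' correlation, (0, 0.3\] weak, (0.3, 0.7) moderate, \[0.7, 1\] strong.
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @param method `"spearman"` or `"pearson"`.
#' @return one-row tibble: `method`, `rho`, `p`, `strength`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length inputs with n >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("undefined correlation: constant input")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  r <- unname(ct$estimate)
  band <- function(a) {
    a <- abs(a)
    if (a == 0) "none" else if (a <= 0.3) "weak" else if (a < 0.7) "moderate" else "strong"
  }
  tibble(method = method, rho = r, p = ct$p.value, strength = band(r))
}
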