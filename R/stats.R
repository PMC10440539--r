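#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic of the standardized sample against the standard
#' normal distribution function, with the p-value from the asymptotic KS
#' distribution (via [stats::ks.test()] on the standardized values).
#'
#' @param x numeric sample, length >= 5, nonzero variance.
#' @return list with `statistic` and `p_value`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5L)
    stop("ks_normality: need at least 5 observations", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("ks_normality: zero-variance sample", call. = FALSE)
  z <- (x - mean(x)) / s
  kt <- suppressWarnings(stats::ks.test(z, "pnorm", exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Paired t test between multilayer and single-layer values
#'
#' Two-sided paired t test on per-patient scalars:
#' `t = mean(d) / (sd(d)/sqrt(n))` with `d = multi - single` and `n - 1`
#' degrees of freedom, plus the KS normality screen of the differences.
#' Identical samples (zero-variance differences) are a degenerate pairing
#' and raise an error.
#'
#' @param multi,single equal-length numeric vectors (n >= 2).
#' @param alpha significance level for the flag (default 0.05).
#' @return list of class `paired_comparison`: `n`, `mean_diff`, `t`, `df`,
#'   `p_value`, `ks_statistic`, `ks_p` (NA when n < 5), `significant`.
#' @export
paired_t <- function(multi, single, alpha = 0.05) {
  if (length(multi) != length(single))
    stop("paired_t: samples must have equal length", call. = FALSE)
  n <- length(multi)
  if (n < 2L) stop("paired_t: need n >= 2 pairs", call. = FALSE)
  d <- multi - single
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0)
    stop("paired_t: zero-variance differences (degenerate pairing)",
         call. = FALSE)
  tstat <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  ks <- if (n >= 5L) ks_normality(d) else
    list(statistic = NA_real_, p_value = NA_real_)
  structure(list(n = n, mean_diff = mean(d), t = tstat, df = n - 1L,
                 p_value = p, ks_statistic = ks$statistic,
                 ks_p = ks$p_value, significant = p < alpha),
            class = "paired_comparison")
}
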