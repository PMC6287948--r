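## Repeatability and heterogeneity statistics: Bland-Altman agreement,
## Wilcoxon signed-rank tests (exact by sign-flip enumeration for small n),
## regional MAD heterogeneity and dorsoventral / apicobasal gradient
## contrasts.

#' Bland-Altman agreement analysis
#'
#' Differences are `b - a`; limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)` with the n-1 SD denominator.  Incomplete
#' pairs (NA in either member) are excluded pairwise.
#'
#' @param a,b paired measurement vectors.
#' @return object of class `bland_altman`: `n`, `mean_diff`, `sd_diff`,
#'   `loa` (lower, upper), `means`, `diffs`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop_input("a and b must have equal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop_input("need at least 2 complete pairs")
  d <- b - a
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(n = length(d), mean_diff = m, sd_diff = s,
                 loa = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
                 means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d  mean diff %.4g  SD %.4g  LoA [%.4g, %.4g]\n",
              x$n, x$mean_diff, x$sd_diff, x$loa[1], x$loa[2]))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of paired differences against pair means with the mean difference
#' and 95% limits of agreement as horizontal lines.
#'
#' @param x a [bland_altman] result.
#' @param ... passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of pair",
                 ylab = "difference (b - a)", ...)
  graphics::abline(h = c(x$mean_diff, x$loa), lty = c(1, 2, 2))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped and ties mid-ranked.  For n <= `exact_max`
#' non-zero differences the two-sided p-value is computed by full
#' enumeration of all 2^n sign assignments of the observed ranks
#' (`p = P(|W - T/2| >= |w - T/2|)`, T = total rank sum); for larger n a
#' normal approximation with the tie-respecting variance `sum(r^2)/4` is
#' used.
#'
#' @param a,b paired measurement vectors.
#' @param exact_max largest n handled exactly (default 12).
#' @return list with `statistic` (W+, sum of positive-difference ranks),
#'   `p_value`, `n` (non-zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 12) {
  if (length(a) != length(b)) stop_input("a and b must have equal length")
  ok <- is.finite(a) & is.finite(b)
  d <- (b - a)[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_input("degenerate pairing: all differences are zero")
  if (n < 5) stop_input("need at least 5 non-zero differences (got %d)", n)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  total <- n * (n + 1) / 2
  if (n <= exact_max) {
    ## all 2^n sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W <- as.numeric(signs %*% r)
    p <- mean(abs(W - total / 2) >= abs(w - total / 2) - 1e-12)
    method <- "exact (sign-flip enumeration)"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - total / 2) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected variance)"
  }
  list(statistic = w, p_value = min(p, 1), n = n, method = method)
}

#' Regional heterogeneity: median absolute difference from the whole lung
#'
#' Defined as the median, over the lung regions, of the absolute difference
#' between each region's median parameter value and the whole-lung median.
#' (This is a region-vs-whole heterogeneity index, not the conventional
#' median absolute deviation from the median.)
#'
#' @param region_medians per-region median values (>= 2 regions).
#' @param whole_median whole-lung median of the same parameter.
#' @return non-negative scalar.
#' @export
regional_mad <- function(region_medians, whole_median) {
  region_medians <- region_medians[is.finite(region_medians)]
  if (length(region_medians) < 2) stop_input("need at least 2 regions")
  stats::median(abs(region_medians - whole_median))
}

#' Regional gradient contrast
#'
#' Dorsoventral: mean over all back (dorsal) regions minus mean over all
#' front (ventral) regions.  Apicobasal: mean over upper minus mean over
#' lower regions, middle slabs excluded.
#'
#' @param summary a [region_summary] data.frame (12-region scheme).
#' @param axis `"dorsoventral"` or `"apicobasal"`.
#' @param parameters columns to contrast.
#' @return named numeric vector, one contrast per parameter.
#' @export
gradient_contrast <- function(summary, axis = c("dorsoventral", "apicobasal"),
                              parameters = c("mtt", "pbf", "pbv")) {
  axis <- match.arg(axis)
  s <- summary[summary$region_id != "whole", , drop = FALSE]
  if (axis == "dorsoventral") {
    hi <- s$depth == "back"; lo <- s$depth == "front"
  } else {
    hi <- s$vertical == "upper"; lo <- s$vertical == "lower"
  }
  if (!any(hi) || !any(lo))
    stop_input("summary lacks the regions required for the %s contrast", axis)
  vapply(parameters,
         function(p) mean(s[[p]][hi]) - mean(s[[p]][lo]),
         numeric(1))
}
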