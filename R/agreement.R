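#' Bland-Altman agreement on relative differences
#'
#' Per-pair relative difference in percent,
#' `100 * (test - reference) / denominator`, with the denominator either the
#' pair mean (standard Bland-Altman for percentage differences, the default)
#' or the reference value (baseline-relative differences). The bias is the
#' mean difference, `sd` the sample standard deviation (n - 1), and the
#' limits of agreement are `bias +/- 1.96 sd`.
#'
#' @param test,reference Paired numeric vectors (same length, >= 2 pairs);
#'   all reference values must be positive.
#' @param denominator_mode `"pair_mean"` or `"reference"`.
#' @return An object of class `agreement_result` with fields `bias_pct`,
#'   `sd_pct`, `loa_low_pct`, `loa_high_pct`, `n_pairs`, `denominator_mode`,
#'   `diff_pct` (the per-pair differences).
#' @examples
#' bland_altman(c(110, 90, 100), c(100, 100, 100))
#' @export
bland_altman <- function(test, reference,
                         denominator_mode = c("pair_mean", "reference")) {
  denominator_mode <- match.arg(denominator_mode)
  test <- as.numeric(test); reference <- as.numeric(reference)
  if (length(test) != length(reference)) stop("test/reference lengths differ")
  if (length(test) < 2) stop("need at least 2 pairs")
  if (any(reference <= 0)) stop("reference values must be positive")
  den <- switch(denominator_mode,
                pair_mean = (test + reference) / 2,
                reference = reference)
  if (any(den <= 0)) stop("non-positive denominator")
  d <- 100 * (test - reference) / den
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias_pct = bias, sd_pct = s,
                 loa_low_pct = bias - 1.96 * s,
                 loa_high_pct = bias + 1.96 * s,
                 n_pairs = length(d),
                 denominator_mode = denominator_mode,
                 diff_pct = d),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> bias %.3f%% (SD %.3f%%), LoA [%.3f, %.3f]%%, n=%d (%s)\n",
              x$bias_pct, x$sd_pct, x$loa_low_pct, x$loa_high_pct, x$n_pairs,
              x$denominator_mode))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Differences `x - y`; zero differences are dropped (Wilcoxon's original
#' rule); absolute differences are ranked with midranks for ties; the
#' statistic `W` is the sum of ranks of the positive differences. The
#' two-sided p-value is exact — full enumeration of all `2^n` sign
#' assignments — when the effective sample size is at most `exact_max`
#' (default 12), otherwise a normal approximation with tie correction and a
#' 0.5 continuity correction is used.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @param exact_max Largest `n_effective` for which full enumeration is used.
#' @return An object of class `wilcoxon_result`: `statistic` (W), `p_value`,
#'   `n_effective`, `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' wilcoxon_paired(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))  # W = 15, p = 0.0625
#' @export
wilcoxon_paired <- function(x, y, exact_max = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate: no nonzero differences")
  r <- rank(abs(d))  # midranks for ties
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # every sign assignment equally likely under the null
    p <- exact_signed_rank_p(r, W)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    # sum(r^2)/4 is the tie-corrected variance (midranks absorb the usual
    # -sum(t^3 - t)/48 correction)
    sigma <- sqrt(sum(r^2) / 4)
    # continuity-corrected two-sided normal approximation
    z <- (W - mu - sign(W - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(statistic = W, p_value = p, n_effective = n, method = method),
            class = "wilcoxon_result")
}

# exact two-sided p by enumerating all 2^n sign vectors:
# p = 2 * min(P(W <= w), P(W >= w)), capped at 1
exact_signed_rank_p <- function(ranks, W) {
  n <- length(ranks)
  # distribution of the positive-rank sum over all sign assignments,
  # built by sequential convolution over each rank's {0, r} contribution
  sums <- 0
  for (r in ranks) sums <- c(sums, sums + r)
  tol <- 1e-9
  p_le <- mean(sums <= W + tol)
  p_ge <- mean(sums >= W - tol)
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W = %.1f, p = %.5g (n_eff = %d, %s)\n",
              x$statistic, x$p_value, x$n_effective, x$method))
  invisible(x)
}
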