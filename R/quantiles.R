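#' Rank-based quantile with the r = p(n+1) rule
#'
#' The nonparametric quantile convention used throughout the package (both
#' for reference-interval percentiles and for the Tukey quartiles): the
#' p-th quantile sits at rank r = p(n+1) among the order statistics, with
#' linear interpolation between adjacent order statistics and the rank
#' clamped to [1, n]. This is `type = 6` interpolation in the usual
#' taxonomy, the convention recommended for nonparametric reference
#' intervals.
#'
#' @param x Numeric vector of finite values.
#' @param p Probabilities in \[0, 1\] (vectorised).
#' @return Numeric vector of quantiles, one per `p`.
#' @examples
#' rank_quantile(1:39, c(0.025, 0.5, 0.975))  # 1, 20, 39
#' @export
rank_quantile <- function(x, p) {
  if (!length(x)) stop("empty vector")
  if (any(!is.finite(x))) stop("non-finite values in x")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  sx <- sort(x)
  n <- length(sx)
  r <- pmin(pmax(p * (n + 1), 1), n)
  lo <- floor(r)
  hi <- ceiling(r)
  sx[lo] + (r - lo) * (sx[hi] - sx[lo])
}
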