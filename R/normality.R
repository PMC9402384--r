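#' Skewness/kurtosis normality screen
#'
#' Screens a sample for normality by the skewness and kurtosis z-tests:
#' the bias-adjusted sample skewness G1 and excess kurtosis G2 (the values
#' mainstream statistical software reports) are divided by their exact
#' small-sample standard errors
#' \deqn{SE_{skew} = \sqrt{6n(n-1)/((n-2)(n+1)(n+3))}}
#' \deqn{SE_{kurt} = 2\,SE_{skew}\sqrt{(n^2-1)/((n-3)(n+5))}}
#' and the sample is judged normal iff both |z| ratios are below 1.96
#' (two 5% two-sided tests). Kurtosis is excess kurtosis, so the criterion
#' is centred at 0 for a normal population.
#'
#' @param values Numeric vector, n >= 8, nonzero variance.
#' @return An object of class `ri_normality`: a list with `n`, `skewness`,
#'   `excess_kurtosis`, `se_skewness`, `se_kurtosis`, `skew_z`, `kurt_z`
#'   and the boolean verdict `is_normal`.
#' @examples
#' assess_normality(rnorm(100))
#' @export
assess_normality <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8L) stop("insufficient sample: need n >= 8, got ", n)
  if (any(!is.finite(values))) stop("non-finite values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("degenerate data: zero variance")
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  se_kurt <- 2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  out <- list(n = n, skewness = G1, excess_kurtosis = G2,
              se_skewness = se_skew, se_kurtosis = se_kurt,
              skew_z = G1 / se_skew, kurt_z = G2 / se_kurt,
              is_normal = abs(G1 / se_skew) < 1.96 &&
                abs(G2 / se_kurt) < 1.96)
  class(out) <- "ri_normality"
  out
}

#' @export
print.ri_normality <- function(x, ...) {
  cat(sprintf(
    "Skewness/kurtosis normality screen (n = %d)\n  skewness %.4f (z = %.2f), excess kurtosis %.4f (z = %.2f)\n  verdict: %s\n",
    x$n, x$skewness, x$skew_z, x$excess_kurtosis, x$kurt_z,
    if (x$is_normal) "normal" else "non-normal"))
  invisible(x)
}

# Box-Cox power transform of a shifted positive vector.
bc_apply <- function(x, lambda, shift = 0) {
  xs <- x + shift
  if (any(xs <= 0)) stop("domain error: x + shift must be positive")
  if (abs(lambda) < 1e-8) log(xs) else (xs^lambda - 1) / lambda
}

bc_inverse <- function(y, lambda, shift = 0) {
  if (abs(lambda) < 1e-8) exp(y) - shift else (lambda * y + 1)^(1 / lambda) - shift
}

# Profile log-likelihood of the one-sample Box-Cox model at lambda.
bc_loglik <- function(x, lambda, shift = 0) {
  xs <- x + shift
  y <- bc_apply(x, lambda, shift)
  n <- length(y)
  s2 <- mean((y - mean(y))^2)
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(xs))
}

#' Box-Cox transformation
#'
#' Transforms a strictly positive sample with the Box-Cox power family,
#' y = ((x + shift)^lambda - 1)/lambda (natural log at lambda = 0). When
#' `lambda` is omitted it is fitted by maximising the profile
#' log-likelihood over the grid lambda in \[-3, 3\] step 0.05, ties broken
#' toward 0, followed by golden-section refinement of the winning cell.
#' If the data contain non-positive values a shift of
#' |min(x)| + half the smallest positive value is applied first (rare
#' subsets can legitimately have zero counts in small children).
#'
#' @param values Strictly positive (after shift) numeric vector.
#' @param lambda Optional fixed exponent; fitted when `NULL`.
#' @return An object of class `ri_boxcox`: list with `lambda`, `shift`,
#'   `transformed` and `profile_loglik`.
#' @examples
#' boxcox_transform(c(1, exp(1), exp(2)), lambda = 0)$transformed  # 0 1 2
#' @export
boxcox_transform <- function(values, lambda = NULL) {
  x <- values[!is.na(values)]
  if (!length(x)) stop("empty input")
  if (any(!is.finite(x))) stop("non-finite values")
  if (stats::var(x) == 0) stop("degenerate data: zero variance")
  shift <- 0
  if (min(x) <= 0) {
    pos <- x[x > 0]
    if (!length(pos)) stop("domain error: no positive values")
    shift <- abs(min(x)) + min(pos) / 2
  }
  if (is.null(lambda)) {
    grid <- seq(-3, 3, by = 0.05)
    ll <- vapply(grid, function(l) bc_loglik(x, l, shift), numeric(1))
    best <- which(ll >= max(ll) - 1e-8)
    i <- best[which.min(abs(grid[best]))]  # ties toward 0
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    lambda <- golden_max(function(l) bc_loglik(x, l, shift), lo, hi)
    # keep the interpretable lambda = 0 when it is effectively optimal
    if (abs(lambda) < 1e-3 &&
        bc_loglik(x, 0, shift) >= bc_loglik(x, lambda, shift) - 1e-6) {
      lambda <- 0
    }
  } else {
    if (!is.finite(lambda)) stop("lambda must be finite")
  }
  out <- list(lambda = lambda, shift = shift,
              transformed = bc_apply(values, lambda, shift),
              profile_loglik = bc_loglik(x, lambda, shift))
  class(out) <- "ri_boxcox"
  out
}

# Golden-section maximisation on [lo, hi].
golden_max <- function(f, lo, hi, tol = 1e-6) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a)
  c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    }
  }
  (a + b) / 2
}

#' @export
print.ri_boxcox <- function(x, ...) {
  cat(sprintf("Box-Cox transform: lambda = %.4f, shift = %g (n = %d)\n",
              x$lambda, x$shift, length(x$transformed)))
  invisible(x)
}
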