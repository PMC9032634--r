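#' Draw from a truncated normal distribution
#'
#' Exact inverse-CDF sampling of `Normal(mean, sd^2)` restricted to
#' `[lower, upper]`.  The quantile inversion is carried out on the log-CDF
#' scale so draws stay accurate when the truncation interval sits far in a
#' tail; the standard-normal symmetry is used to always work in the lower
#' tail.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale, `sd > 0`.
#' @param lower,upper Truncation bounds, `lower < upper` (may be infinite).
#' @return Numeric vector of `n` draws in `[lower, upper]`.
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (lower >= upper) stop("need lower < upper", call. = FALSE)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  ## flip into the lower tail so pnorm() keeps precision
  s <- a + b
  flip <- !is.nan(s) && s > 0 # NaN when the interval is (-Inf, Inf): no flip
  if (flip) {
    tmp <- a; a <- -b; b <- -tmp
  }
  la <- stats::pnorm(a, log.p = TRUE)
  lb <- stats::pnorm(b, log.p = TRUE)
  lmass <- lb + log1p(-exp(la - lb))
  if (!is.finite(lmass) || lmass < log(1e-300)) {
    stop(sprintf(
      "truncation interval [%g, %g] carries essentially no probability mass",
      lower, upper), call. = FALSE)
  }
  u <- stats::runif(n)
  ## quantile at plo + u * (phi - plo), assembled in log space
  lq <- lb + log(exp(la - lb) * (1 - u) + u)
  z <- stats::qnorm(lq, log.p = TRUE)
  if (flip) z <- -z
  pmin(pmax(mean + sd * z, lower), upper)
}

#' Draw from a truncated inverse-gamma distribution
#'
#' Exact inverse-CDF sampling of `InvGamma(shape, scale)` (density
#' proportional to `x^-(shape+1) exp(-scale/x)`) restricted to
#' `[lower, upper]`.  Uses the identity `X ~ InvGamma(a, b)` iff
#' `1/X ~ Gamma(a, rate = b)`, working with upper-tail gamma
#' probabilities on the log scale for stability.
#'
#' @param n Number of draws.
#' @param shape,scale Shape and scale parameters, both `> 0`.
#' @param lower,upper Truncation bounds, `0 <= lower < upper`.
#' @return Numeric vector of `n` draws in `[lower, upper]`.
#' @export
rtinvgamma <- function(n, shape, scale, lower = 0, upper = Inf) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be > 0", call. = FALSE)
  if (lower < 0 || lower >= upper) stop("need 0 <= lower < upper", call. = FALSE)
  ## F(x) = P(Gamma(shape, rate=scale) >= 1/x), increasing in x
  lFlo <- stats::pgamma(1 / lower, shape, rate = scale,
                        lower.tail = FALSE, log.p = TRUE) # -Inf when lower = 0
  lFhi <- stats::pgamma(1 / upper, shape, rate = scale,
                        lower.tail = FALSE, log.p = TRUE) # 0 when upper = Inf
  if (lower == 0) lFlo <- -Inf
  lmass <- lFhi + log1p(-exp(lFlo - lFhi))
  if (!is.finite(lmass) || lmass < log(1e-300)) {
    stop(sprintf(
      "truncation interval [%g, %g] carries essentially no probability mass",
      lower, upper), call. = FALSE)
  }
  u <- stats::runif(n)
  lq <- lFhi + log(exp(lFlo - lFhi) * (1 - u) + u)
  x <- 1 / stats::qgamma(lq, shape, rate = scale,
                         lower.tail = FALSE, log.p = TRUE)
  pmin(pmax(x, lower), upper)
}
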