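#' Summarise posterior draws
#'
#' Pooled-chain medians and equal-tailed 95% credible intervals (2.5th and
#' 97.5th empirical percentiles) for the geometric mean `exp(mu)`, the
#' geometric standard deviation `exp(sigma)` and the 95th percentile
#' `exp(mu + 1.6449 sigma)`.  The P95 is transformed per draw and then
#' summarised, so its median is the median of the P95 posterior, not a
#' plug-in of parameter medians.
#'
#' @param draws A `"posterior_draws"` object (see [gibbs_lognormal()]).
#' @return A data frame with one row per quantity (`gm`, `gsd`, `p95`) and
#'   columns `quantity`, `median`, `cri_lower`, `cri_upper`.
#' @export
summarize_posterior <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  mu <- as.vector(draws$mu)
  sigma <- as.vector(draws$sigma)
  if (length(mu) == 0L) stop("no draws to summarise", call. = FALSE)
  q3 <- function(x) unname(stats::quantile(x, c(0.5, 0.025, 0.975), type = 7))
  vals <- rbind(gm = q3(exp(mu)),
                gsd = q3(exp(sigma)),
                p95 = q3(exp(mu + Z95 * sigma)))
  data.frame(quantity = rownames(vals),
             median = vals[, 1], cri_lower = vals[, 2], cri_upper = vals[, 3],
             row.names = NULL)
}

#' Posterior probabilities of the exposure-control categories
#'
#' Fraction of posterior draws whose P95 falls in each regulatory band
#' relative to the exposure limit: category 1 `[0, 0.1 oel)`, category 2
#' `[0.1 oel, 0.5 oel)`, category 3 `[0.5 oel, oel)`, category 4
#' `[oel, Inf)`.  Bands are lower-inclusive, matching the code of
#' practice's ">=" conventions.
#'
#' @param draws A `"posterior_draws"` object, or a numeric vector of P95
#'   draws (mg/m3).
#' @param oel Occupational exposure limit, mg/m3.
#' @return Named numeric vector `c(p1, p2, p3, p4)` summing to 1.
#' @export
category_probabilities <- function(draws, oel = DEFAULT_OEL) {
  if (!is.finite(oel) || oel <= 0) stop("oel must be > 0", call. = FALSE)
  p95 <- if (inherits(draws, "posterior_draws")) {
    exp(as.vector(draws$mu) + Z95 * as.vector(draws$sigma))
  } else {
    as.numeric(draws)
  }
  if (length(p95) == 0L) stop("no draws", call. = FALSE)
  cat_idx <- findInterval(p95, c(0.1, 0.5, 1) * oel) + 1L
  p <- tabulate(cat_idx, nbins = 4L) / length(p95)
  names(p) <- paste0("p", 1:4)
  p
}

## Split each column (chain) of a draw matrix in half.
split_chains <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2L) stop("chains too short to split", call. = FALSE)
  ## drop the middle draw when n is odd
  cbind(x[seq_len(half), , drop = FALSE],
        x[seq.int(n - half + 1L, n), , drop = FALSE])
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed on split chains: each chain is
#' halved, `W` is the mean within-half variance, `B/n` the variance of the
#' half means, and
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \, W + B/n}{W}}.}
#' Values at or below 1.05 are conventionally taken as converged.
#'
#' @param x A matrix of draws, iterations x chains (at least 2 chains of
#'   length at least 10), or a `"posterior_draws"` object (then the maximum
#'   of the `mu` and `sigma` R-hats is returned).
#' @return The split-R-hat value.
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "posterior_draws")) {
    return(max(gelman_rubin(x$mu), gelman_rubin(x$sigma)))
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("R-hat needs at least 2 chains", call. = FALSE)
  if (nrow(x) < 10L) stop("chains must have length >= 10", call. = FALSE)
  h <- split_chains(x)
  n <- nrow(h)
  w <- mean(apply(h, 2, stats::var))
  b_over_n <- stats::var(colMeans(h))
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

## FFT autocovariance (denominator n), lags 0..n-1.
autocov_fft <- function(y) {
  n <- length(y)
  y <- y - mean(y)
  m <- stats::nextn(2L * n)
  f <- stats::fft(c(y, rep(0, m - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / m
  ac[seq_len(n)] / n
}

## Core multi-chain ESS (Geyer initial-monotone-sequence truncation) on a
## matrix of split chains.
ess_core <- function(h) {
  n <- nrow(h)
  m <- ncol(h)
  vars <- apply(h, 2, stats::var)
  w <- mean(vars)
  var_plus <- w * (n - 1) / n + stats::var(colMeans(h))
  if (!is.finite(var_plus) || var_plus == 0) return(0)
  acov <- vapply(seq_len(m), function(j) autocov_fft(h[, j]), numeric(n))
  s_t <- rowMeans(acov)
  rho <- 1 - (w - s_t) / var_plus
  ## Geyer pairs P_k = rho_{2k} + rho_{2k+1}
  max_pairs <- floor(n / 2) - 1L
  p <- numeric(0)
  for (k in seq_len(max_pairs)) {
    pk <- rho[2 * k - 1] + rho[2 * k]
    if (pk <= 0) break
    p <- c(p, pk)
  }
  if (length(p) == 0L) return(n * m)
  p <- cummin(p) # enforce monotone non-increasing
  tau <- max(-1 + 2 * sum(p), 1 / (n * m)) # guard against negative tau
  n * m / tau
}

#' Effective sample size (bulk and tail)
#'
#' Autocorrelation-based effective sample size with Geyer's
#' initial-monotone truncation, computed on split chains.  `kind = "bulk"`
#' rank-normalises the pooled draws first (robust to heavy tails);
#' `kind = "tail"` is the minimum of the ESS of the indicator draws for the
#' 5% and 95% pooled quantiles, measuring how reliably the tails are
#' resolved.
#'
#' @param x A matrix of draws, iterations x chains (at least 2 chains).
#' @param kind `"bulk"` or `"tail"`.
#' @return The effective sample size (0, with a warning, for a constant
#'   chain).
#' @export
effective_sample_size <- function(x, kind = c("bulk", "tail")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("ESS needs at least 2 chains", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("constant chain: effective sample size is undefined, returning 0")
    return(0)
  }
  rank_normalize <- function(v) {
    r <- rank(v, ties.method = "average")
    stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  }
  if (kind == "bulk") {
    z <- matrix(rank_normalize(as.vector(x)), nrow(x), ncol(x))
    return(ess_core(split_chains(z)))
  }
  ess_q <- function(q) {
    ind <- (x <= stats::quantile(x, q, type = 7)) * 1
    if (stats::sd(ind) == 0) return(0)
    ess_core(split_chains(ind))
  }
  min(ess_q(0.05), ess_q(0.95))
}

#' Convergence diagnostics for a fit
#'
#' Split-R-hat and bulk/tail effective sample sizes for `mu` and `sigma`,
#' with pass flags at the conventional thresholds: R-hat at most 1.05 and
#' more than 100 effective draws per chain.
#'
#' @param draws A `"posterior_draws"` object.
#' @return A data frame with one row per parameter and columns `parameter`,
#'   `rhat`, `ess_bulk`, `ess_tail`, `converged` (R-hat rule) and
#'   `ess_ok` (per-chain ESS rule).
#' @export
diagnose <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  n_chains <- ncol(draws$mu)
  one <- function(name, m) {
    rhat <- gelman_rubin(m)
    eb <- effective_sample_size(m, "bulk")
    et <- effective_sample_size(m, "tail")
    data.frame(parameter = name, rhat = rhat,
               ess_bulk = eb, ess_tail = et,
               converged = rhat <= 1.05,
               ess_ok = min(eb, et) > 100 * n_chains)
  }
  rbind(one("mu", draws$mu), one("sigma", draws$sigma))
}
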