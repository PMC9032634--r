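#' Lognormal log-likelihood from sufficient statistics
#'
#' Log-likelihood of lognormal concentrations with log-scale mean `mu` and
#' standard deviation `sigma`, evaluated through the sufficient statistics
#' `(n, ybar, s_y)`:
#' \deqn{\ell = -\tfrac{n}{2}\log(2\pi) - n\bar y - n\log\sigma -
#'   \frac{(n-1)s_y^2 + n(\bar y - \mu)^2}{2\sigma^2}}
#' The full additive constant is kept (including the Jacobian term
#' `-n * ybar` from the 1/y factor of the lognormal density), so the value
#' equals `sum(dlnorm(y, mu, sigma, log = TRUE))` on the raw data.
#'
#' @param stats A [heg_stats()] object.
#' @param mu,sigma Parameter values; vectorised, `sigma > 0`.
#' @return Log-likelihood value(s).
#' @export
loglik_lognormal <- function(stats, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  n <- stats$n
  ss <- (n - 1) * stats$s_y^2 + n * (stats$ybar - mu)^2
  -n / 2 * log(2 * pi) - n * stats$ybar - n * log(sigma) - ss / (2 * sigma^2)
}

#' Gibbs sampler for the lognormal exposure model
#'
#' Samples the posterior of `(mu, sigma)` for one HEG by alternating exact
#' draws from the truncated full conditionals.
#'
#' Under the flat [uniform_prior()] on `(mu, sigma)`:
#' \itemize{
#'   \item `mu | sigma^2 ~ Normal(ybar, sigma^2 / n)` truncated to the `mu`
#'     bounds;
#'   \item `sigma^2 | mu ~ InvGamma((n - 1) / 2, SS / 2)` truncated to the
#'     squared `sigma` bounds, with `SS = (n-1) s_y^2 + n (ybar - mu)^2`
#'     (the extra factor `(sigma^2)^(-1/2)` from flatness on the sigma —
#'     not sigma-squared — scale folds into the shape).
#' }
#' Under an [informative_prior()]:
#' \itemize{
#'   \item `mu | sigma^2 ~ Normal(m*, v*)` with
#'     `v* = 1 / (n / sigma^2 + 1 / v0)` and
#'     `m* = v* (n ybar / sigma^2 + m0 / v0)`, truncated;
#'   \item `sigma^2 | mu ~ InvGamma(a0 + n / 2, b0 + SS / 2)`, truncated.
#' }
#' When the [p95_constraint()] is active, both conditionals are further
#' truncated so every retained draw satisfies
#' `exp(mu + 1.6449 sigma) < k * oel` — the constraint defines the support
#' of the joint posterior, so it must cut both conditionals.
#'
#' Chains are initialised overdispersed around `(ybar, s_y)`
#' (`mu0 = ybar +/- s_y`, `sigma0 = s_y * {0.5, 1, 2}`, clipped to the
#' bounds) and warmup draws are discarded.
#'
#' @param stats A [heg_stats()] object with `n >= 2`.
#' @param prior A [uniform_prior()] or [informative_prior()].
#' @param constraint A [p95_constraint()]; disabled by default.
#' @param config An [mcmc_config()].
#' @return An object of class `"posterior_draws"`: a list with matrices
#'   `mu` and `sigma` (`n_iter` rows x `n_chains` columns), the inputs,
#'   and `bound_hits`, the share of retained draws falling in the outer 1%
#'   of each active truncation interval (a binding bound shows up as a
#'   large share).
#' @examples
#' st <- stats_from_table(52, gm = 0.42, gsd = 3.29)
#' fit <- gibbs_lognormal(st, uniform_prior(),
#'                        config = mcmc_config(n_iter = 500, n_warmup = 100))
#' summarize_posterior(fit)
#' @export
gibbs_lognormal <- function(stats, prior,
                            constraint = p95_constraint(),
                            config = mcmc_config()) {
  stopifnot(inherits(stats, "heg_stats"))
  if (!inherits(prior, "uniform_prior") && !inherits(prior, "informative_prior")) {
    stop("prior must be a uniform_prior or informative_prior", call. = FALSE)
  }
  stopifnot(inherits(constraint, "p95_constraint"),
            inherits(config, "mcmc_config"))
  if (stats$n < 2L) stop("Gibbs fit needs n >= 2", call. = FALSE)
  informative <- inherits(prior, "informative_prior")
  n <- stats$n
  ybar <- stats$ybar
  s2 <- stats$s_y^2

  mu_lo <- prior$mu_lower
  mu_hi <- prior$mu_upper
  if (informative) {
    s2_lo <- prior$sigma2_lower
    s2_hi <- prior$sigma2_upper
  } else {
    s2_lo <- prior$sigma_lower^2
    s2_hi <- prior$sigma_upper^2
  }
  cap <- constraint$cap_log
  if (constraint$enabled && cap - Z95 * sqrt(s2_lo) <= mu_lo) {
    stop(sprintf(
      "P95 cap log(k*oel) = %.3f leaves no room above mu_lower = %.3f at sigma2_lower = %.3f",
      cap, mu_lo, s2_lo), call. = FALSE)
  }

  n_keep <- config$n_iter
  n_chains <- config$n_chains
  thin <- config$thin
  n_total <- config$n_warmup + n_keep * thin

  ## overdispersed starts around the data moments, clipped inside the box
  clip <- function(x, lo, hi) pmin(pmax(x, lo + 1e-9), hi - 1e-9)
  mu_starts <- clip(ybar + c(-1, 1) * max(stats$s_y, 0.1), mu_lo,
                    if (constraint$enabled) min(mu_hi, cap) else mu_hi)
  sd_starts <- clip(max(stats$s_y, sqrt(s2_lo) + 0.05) * c(0.5, 1, 2),
                    sqrt(s2_lo), sqrt(s2_hi))

  mu_out <- matrix(NA_real_, n_keep, n_chains)
  sig_out <- matrix(NA_real_, n_keep, n_chains)

  set.seed(config$seed)
  for (ch in seq_len(n_chains)) {
    mu <- mu_starts[(ch - 1L) %% 2L + 1L]
    sig2 <- sd_starts[(ch - 1L) %% 3L + 1L]^2
    kept <- 0L
    for (i in seq_len(n_total)) {
      ## mu | sigma^2
      if (informative) {
        v <- 1 / (n / sig2 + 1 / prior$v0)
        m <- v * (n * ybar / sig2 + prior$m0 / prior$v0)
      } else {
        v <- sig2 / n
        m <- ybar
      }
      hi <- if (constraint$enabled) min(mu_hi, cap - Z95 * sqrt(sig2)) else mu_hi
      if (hi <= mu_lo) {
        stop(sprintf(
          "empty mu truncation: [%.3f, %.3f] under the active P95 cap",
          mu_lo, hi), call. = FALSE)
      }
      mu <- rtnorm(1L, m, sqrt(v), mu_lo, hi)
      ## sigma^2 | mu
      ss <- (n - 1) * s2 + n * (ybar - mu)^2
      if (informative) {
        a <- prior$a0 + n / 2
        b <- prior$b0 + ss / 2
      } else {
        a <- (n - 1) / 2
        b <- ss / 2
      }
      s_hi <- if (constraint$enabled) min(s2_hi, ((cap - mu) / Z95)^2) else s2_hi
      if (s_hi <= s2_lo) {
        stop(sprintf(
          "empty sigma^2 truncation: [%.3g, %.3g] under the active P95 cap",
          s2_lo, s_hi), call. = FALSE)
      }
      sig2 <- rtinvgamma(1L, a, b, s2_lo, s_hi)
      if (i > config$n_warmup && (i - config$n_warmup) %% thin == 0L) {
        kept <- kept + 1L
        mu_out[kept, ch] <- mu
        sig_out[kept, ch] <- sqrt(sig2)
      }
    }
  }

  edge_share <- function(x, lo, hi) {
    if (!is.finite(lo) || !is.finite(hi)) return(c(lower = 0, upper = 0))
    w <- (hi - lo) * 0.01
    c(lower = mean(x <= lo + w), upper = mean(x >= hi - w))
  }
  mu_edge <- edge_share(mu_out, mu_lo, mu_hi)
  s2_edge <- edge_share(sig_out^2, s2_lo, s2_hi)
  cap_share <- if (constraint$enabled)
    mean(mu_out + Z95 * sig_out >= cap - 0.01 * abs(cap)) else 0

  structure(list(mu = mu_out, sigma = sig_out,
                 stats = stats, prior = prior, constraint = constraint,
                 config = config,
                 bound_hits = c(mu_lower = unname(mu_edge["lower"]),
                                mu_upper = unname(mu_edge["upper"]),
                                sigma2_lower = unname(s2_edge["lower"]),
                                sigma2_upper = unname(s2_edge["upper"]),
                                p95_cap = cap_share)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d chains x %d iterations (%s prior)\n",
              ncol(x$mu), nrow(x$mu),
              if (inherits(x$prior, "informative_prior")) "informative"
              else "uniform"))
  s <- summarize_posterior(x)
  print(s)
  invisible(x)
}

#' Pooled draws as a data frame
#'
#' @param x A `"posterior_draws"` object.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return A data frame with columns `chain`, `iter`, `mu`, `sigma`, and
#'   the per-draw derived quantities `gm`, `gsd`, `p95`.
#' @export
as.data.frame.posterior_draws <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  n_iter <- nrow(x$mu)
  n_chains <- ncol(x$mu)
  mu <- as.vector(x$mu)
  sigma <- as.vector(x$sigma)
  data.frame(chain = rep(seq_len(n_chains), each = n_iter),
             iter = rep(seq_len(n_iter), times = n_chains),
             mu = mu, sigma = sigma,
             gm = exp(mu), gsd = exp(sigma),
             p95 = exp(mu + Z95 * sigma))
}
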