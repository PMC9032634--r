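#' Non-informative uniform prior on (mu, sigma)
#'
#' A flat prior on the log-scale mean `mu` and log-scale standard deviation
#' `sigma` over a bounded box.  The defaults span GM from 0.001 to
#' 100 mg/m3 and GSD from 1.05 to 10 — wide enough to be effectively flat
#' for any realistic dust-exposure dataset while keeping the posterior
#' proper.
#'
#' @param mu_lower,mu_upper Bounds on `mu` (log mg/m3).
#' @param sigma_lower,sigma_upper Bounds on `sigma` (`> 0`).
#' @return An object of class `"uniform_prior"`.
#' @export
uniform_prior <- function(mu_lower = log(0.001), mu_upper = log(100),
                          sigma_lower = log(1.05), sigma_upper = log(10)) {
  if (mu_lower >= mu_upper) stop("need mu_lower < mu_upper", call. = FALSE)
  if (sigma_lower < 0 || sigma_lower >= sigma_upper) {
    stop("need 0 <= sigma_lower < sigma_upper", call. = FALSE)
  }
  structure(list(mu_lower = mu_lower, mu_upper = mu_upper,
                 sigma_lower = sigma_lower, sigma_upper = sigma_upper),
            class = "uniform_prior")
}

#' Informative normal/inverse-gamma prior
#'
#' Conjugate-style informative prior: `mu ~ Normal(m0, v0)` truncated to
#' `[mu_lower, mu_upper]` and `sigma^2 ~ InvGamma(a0, b0)` truncated to
#' `[sigma2_lower, sigma2_upper]`.  Usually built from historical data via
#' [elicit_informative_prior()].
#'
#' @param m0 Prior mean of `mu` (log mg/m3).
#' @param v0 Prior variance of `mu`, `> 0`.
#' @param a0 Inverse-gamma shape, `> 0`.
#' @param b0 Inverse-gamma scale, `> 0`.
#' @param n0 Prior sample size the parameters were derived from (metadata).
#' @param mu_lower,mu_upper Truncation bounds on `mu`.
#' @param sigma2_lower,sigma2_upper Truncation bounds on `sigma^2`.
#' @return An object of class `"informative_prior"`.
#' @export
informative_prior <- function(m0, v0, a0, b0, n0 = NA_integer_,
                              mu_lower = log(0.001), mu_upper = log(100),
                              sigma2_lower = log(1.05)^2,
                              sigma2_upper = log(10)^2) {
  if (!is.finite(v0) || v0 <= 0) stop("v0 must be > 0", call. = FALSE)
  if (a0 <= 0 || b0 <= 0) stop("a0 and b0 must be > 0", call. = FALSE)
  if (mu_lower >= mu_upper) stop("need mu_lower < mu_upper", call. = FALSE)
  if (sigma2_lower < 0 || sigma2_lower >= sigma2_upper) {
    stop("need 0 <= sigma2_lower < sigma2_upper", call. = FALSE)
  }
  structure(list(m0 = m0, v0 = v0, a0 = a0, b0 = b0, n0 = n0,
                 mu_lower = mu_lower, mu_upper = mu_upper,
                 sigma2_lower = sigma2_lower, sigma2_upper = sigma2_upper),
            class = "informative_prior")
}

#' Elicit an informative prior from historical data
#'
#' Treats a historical campaign as a notional prior sample of size `n0`
#' with log-scale mean `ybar0` and variance `s2y0`.  The prior is then
#' `mu ~ Normal(ybar0, s2y0 / n0)` and
#' `sigma^2 ~ InvGamma((n0 - 1) / 2, (n0 - 1) * s2y0 / 2)`, the scaled
#' chi-square form implied by `(n0 - 1) s2y0 / sigma^2 ~ chisq(n0 - 1)`.
#' Both conditionals are truncated to the bound box.
#'
#' Two eliciting modes:
#' \describe{
#'   \item{`moments`}{(default) use the historical campaign's own log-scale
#'     moments (`ybar`, `s_y^2`) but down-weight them to a prior sample
#'     size of `n0`.  Deterministic given the summary statistics.}
#'   \item{`subsample`}{draw `n0` historical records without replacement
#'     under `seed` and use that subsample's log moments — the field's
#'     customary "prior sample of five".}
#' }
#'
#' The default `mu` upper bound follows the P95 cap when one is active
#' (`log(k * oel)`), otherwise a wide cap of `log(100)`.
#'
#' @param past Historical data: a data frame of measurements or (moments
#'   mode only) a [heg_stats()] object.
#' @param n0 Prior sample size, `>= 2` (default 5, the customary small
#'   prior weight that keeps the posterior anchored to current data).
#' @param mode `"moments"` or `"subsample"`.
#' @param seed Seed for subsample mode.
#' @param oel,k Exposure limit and P95 cap multiplier used for the default
#'   `mu` upper bound; `k = Inf` (no cap) gives `mu_upper = log(100)`.
#' @param mu_lower,mu_upper,sigma2_lower,sigma2_upper Truncation bounds;
#'   `mu_upper = NULL` selects the default described above.
#' @return An object of class `"informative_prior"`.
#' @examples
#' past <- stats_from_table(20, gm = 1.51, gsd = 2.30)
#' pr <- elicit_informative_prior(past, n0 = 5)
#' c(pr$m0, pr$v0, pr$a0, pr$b0)
#' @export
elicit_informative_prior <- function(past, n0 = 5L,
                                     mode = c("moments", "subsample"),
                                     seed = NULL,
                                     oel = DEFAULT_OEL, k = Inf,
                                     mu_lower = log(0.001), mu_upper = NULL,
                                     sigma2_lower = log(1.05)^2,
                                     sigma2_upper = log(10)^2) {
  mode <- match.arg(mode)
  n0 <- as.integer(n0)
  if (is.na(n0) || n0 < 2L) stop("n0 must be >= 2", call. = FALSE)
  if (mode == "moments") {
    st <- if (inherits(past, "heg_stats")) past else summarize_heg(past)
    ybar0 <- st$ybar
    s2y0 <- st$s_y^2
  } else {
    if (inherits(past, "heg_stats")) {
      stop("subsample mode needs raw historical records", call. = FALSE)
    }
    past <- validate_measurements(past)
    if (n0 > nrow(past)) {
      stop("n0 exceeds the number of historical records", call. = FALSE)
    }
    idx <- if (is.null(seed)) sample(nrow(past), n0) else
      local_seed(seed, sample(nrow(past), n0))
    y0 <- log(past$concentration[idx])
    ybar0 <- mean(y0)
    s2y0 <- stats::var(y0)
  }
  if (!is.finite(s2y0) || s2y0 <= 0) {
    stop("historical log-variance is zero; the elicited prior is degenerate",
         call. = FALSE)
  }
  if (is.null(mu_upper)) {
    mu_upper <- if (is.finite(k)) log(k * oel) else log(100)
  }
  informative_prior(m0 = ybar0, v0 = s2y0 / n0,
                    a0 = (n0 - 1) / 2, b0 = (n0 - 1) * s2y0 / 2,
                    n0 = n0,
                    mu_lower = mu_lower, mu_upper = mu_upper,
                    sigma2_lower = sigma2_lower, sigma2_upper = sigma2_upper)
}

#' Joint constraint on the posterior 95th percentile
#'
#' Optionally restricts the posterior to `{exp(mu + 1.6449 sigma) < k * oel}`,
#' i.e. P95 below `k` times the exposure limit.  Disabled by default
#' (`k = Inf`).
#'
#' @param k Cap multiplier, `> 0`; `Inf` disables the constraint.
#' @param oel Occupational exposure limit, mg/m3.
#' @return An object of class `"p95_constraint"`.
#' @export
p95_constraint <- function(k = Inf, oel = DEFAULT_OEL) {
  if (!is.numeric(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  if (oel <= 0) stop("oel must be > 0", call. = FALSE)
  structure(list(enabled = is.finite(k), k = k, oel = oel,
                 cap_log = if (is.finite(k)) log(k * oel) else Inf),
            class = "p95_constraint")
}

#' MCMC settings for the Gibbs sampler
#'
#' @param n_iter Post-warmup draws kept per chain (default 20000).
#' @param n_warmup Warmup iterations discarded per chain (default 2000).
#' @param n_chains Number of chains, `>= 2` so split-R-hat is defined
#'   (default 4).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @param thin Keep every `thin`-th post-warmup draw (default 1).
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_iter = 20000L, n_warmup = 2000L, n_chains = 4L,
                        seed = 1L, thin = 1L) {
  n_iter <- as.integer(n_iter); n_warmup <- as.integer(n_warmup)
  n_chains <- as.integer(n_chains); thin <- as.integer(thin)
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  if (n_warmup < 0L) stop("n_warmup must be >= 0", call. = FALSE)
  if (n_chains < 2L) stop("n_chains must be >= 2 (R-hat needs >= 2 chains)",
                          call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  structure(list(n_iter = n_iter, n_warmup = n_warmup,
                 n_chains = n_chains, seed = as.integer(seed), thin = thin),
            class = "mcmc_config")
}
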