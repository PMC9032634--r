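# Build a posterior_draws shell around given draw matrices.
fake_draws <- function(mu, sigma) {
  structure(list(mu = as.matrix(mu), sigma = as.matrix(sigma)),
            class = "posterior_draws")
}

test_that("posterior summaries follow the per-draw transform", {
  # point mass
  d <- fake_draws(matrix(log(2), 100, 2), matrix(0, 100, 2))
  s <- summarize_posterior(d)
  expect_equal(s$median, c(2, 1, 2))
  expect_equal(s$cri_lower, s$cri_upper)

  # closed-form P95 of a degenerate posterior
  d2 <- fake_draws(matrix(log(1.52), 50, 2), matrix(log(2.55), 50, 2))
  s2 <- summarize_posterior(d2)
  expect_equal(s2$median[s2$quantity == "p95"], 1.52 * 2.55^1.6449,
               tolerance = 1e-12)
  expect_equal(s2$median[s2$quantity == "p95"], 7.09, tolerance = 1e-2)

  # transform-then-summarise: the P95 median is the empirical quantile of
  # exp(mu + z * sigma), not the transform of the parameter medians
  set.seed(3)
  mu <- matrix(rnorm(2000, 0, 0.5), ncol = 2)
  sigma <- matrix(exp(rnorm(2000, 0, 0.4)), ncol = 2)
  s3 <- summarize_posterior(fake_draws(mu, sigma))
  p95 <- exp(as.vector(mu) + 1.6449 * as.vector(sigma))
  expect_equal(s3$median[s3$quantity == "p95"],
               unname(quantile(p95, 0.5, type = 7)), tolerance = 1e-12)
  plugin <- exp(median(mu) + 1.6449 * median(sigma))
  expect_false(isTRUE(all.equal(s3$median[s3$quantity == "p95"], plugin,
                                tolerance = 1e-6)))
})

test_that("category probabilities partition the draws", {
  expect_equal(unname(category_probabilities(c(0.1, 0.3, 1.5, 2.5), oel = 2)),
               rep(0.25, 4))
  expect_equal(unname(category_probabilities(c(5, 7, 9), oel = 2)),
               c(0, 0, 0, 1))

  set.seed(4)
  p95 <- exp(rnorm(5000, 0.5, 1))
  p <- category_probabilities(p95, oel = 2)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # multiplying all draws up never decreases the top-category probability
  p_up <- category_probabilities(p95 * 1.7, oel = 2)
  expect_gte(p_up[["p4"]], p[["p4"]])
})

test_that("split-R-hat matches direct formula evaluation", {
  # hand-checkable toy: two identical monotone chains of length 10;
  # the oracle evaluates the split formula from scratch
  x <- cbind(1:10, 1:10)
  h <- cbind(x[1:5, ], x[6:10, ])             # four split halves
  w <- mean(apply(h, 2, var))                 # within-half variance
  b_over_n <- var(colMeans(h))                # between-half variance of means
  expected <- sqrt(((5 - 1) / 5 * w + b_over_n) / w)
  expect_equal(gelman_rubin(x), expected, tolerance = 1e-12)
  expect_error(gelman_rubin(matrix(1:20, ncol = 1)), "2 chains")
})

test_that("R-hat separates converged from divergent chains", {
  set.seed(5)
  same <- cbind(rnorm(5000), rnorm(5000))
  expect_gte(gelman_rubin(same), 0.99)
  expect_lte(gelman_rubin(same), 1.01)

  apart <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(gelman_rubin(apart), 1.5)
})

test_that("effective sample size matches iid and AR(1) closed forms", {
  set.seed(6)
  iid <- matrix(rnorm(4000), ncol = 4)
  expect_equal(effective_sample_size(iid, "bulk"), 4000,
               tolerance = 0.15)
  expect_gt(effective_sample_size(iid, "tail"), 0.5 * 4000)

  # AR(1) with phi = 0.5: ESS = n (1 - phi) / (1 + phi) = n / 3
  phi <- 0.5
  n <- 10000
  ar <- sapply(1:4, function(i) {
    as.vector(arima.sim(list(ar = phi), n, sd = sqrt(1 - phi^2)))
  })
  expect_equal(effective_sample_size(ar, "bulk"), 4 * n / 3,
               tolerance = 0.15)

  const <- matrix(1, 100, 2)
  expect_warning(e0 <- effective_sample_size(const, "bulk"), "constant")
  expect_equal(e0, 0)
})

test_that("diagnose flags convergence and per-chain ESS", {
  st <- stats_from_table(30, 1.0, 2.5)
  fit <- gibbs_lognormal(st, uniform_prior(), config = quick_mcmc(seed = 13))
  dg <- diagnose(fit)
  expect_equal(dg$parameter, c("mu", "sigma"))
  expect_true(all(dg$rhat >= 0.99))
  expect_true(all(dg$converged))
  expect_true(all(dg$ess_ok)) # Gibbs draws here are nearly independent
})
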