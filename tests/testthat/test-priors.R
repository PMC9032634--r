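test_that("moments-mode elicitation reproduces the closed-form prior", {
  past <- stats_from_table(20, 1.51, 2.30)
  pr <- elicit_informative_prior(past, n0 = 5)
  expect_s3_class(pr, "informative_prior")
  expect_equal(pr$m0, log(1.51), tolerance = 1e-12)
  expect_equal(pr$v0, log(2.30)^2 / 5, tolerance = 1e-12)
  expect_equal(pr$a0, 2)
  expect_equal(pr$b0, 2 * log(2.30)^2, tolerance = 1e-12)
  # spot values
  expect_equal(pr$m0, 0.4121, tolerance = 1e-3)
  expect_equal(pr$v0, 0.1387, tolerance = 1e-3)

  # smallest legal prior sample
  tiny <- elicit_informative_prior(heg_stats(2, 0, 1), n0 = 2)
  expect_equal(tiny$a0, 0.5)
  expect_equal(tiny$b0, 0.5)
})

test_that("subsample-mode elicitation is deterministic given the seed", {
  past <- generate_heg(30, gm = 0.8, gsd = 2.4, seed = 7, campaign = "past")
  a <- elicit_informative_prior(past, n0 = 5, mode = "subsample", seed = 10)
  b <- elicit_informative_prior(past, n0 = 5, mode = "subsample", seed = 10)
  expect_identical(a, b)
  expect_error(
    elicit_informative_prior(past, n0 = 31, mode = "subsample", seed = 1),
    "exceeds")
})

test_that("degenerate historical data is rejected", {
  expect_error(elicit_informative_prior(heg_stats(5, 0, 0), n0 = 5),
               "degenerate")
})

test_that("the default mu cap follows the active P95 constraint", {
  past <- stats_from_table(20, 1.51, 2.30)
  capped <- elicit_informative_prior(past, n0 = 5, k = 2, oel = 2)
  expect_equal(capped$mu_upper, log(4))
  wide <- elicit_informative_prior(past, n0 = 5)
  expect_equal(wide$mu_upper, log(100))
})

test_that("configuration objects validate their inputs", {
  expect_error(mcmc_config(n_chains = 1), "chains")
  expect_error(uniform_prior(mu_lower = 1, mu_upper = 0), "mu_lower")
  expect_error(informative_prior(0, -1, 2, 2), "v0")
  expect_error(p95_constraint(k = -1), "k")
  expect_false(p95_constraint()$enabled)
  expect_true(p95_constraint(k = 2)$enabled)
})
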