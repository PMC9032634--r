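test_that("measurement CSV round-trips and rejects malformed input", {
  recs <- records_of(c(0.8, 1.4, 2.6), heg_id = "HEG Z", year = 2019L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(recs, path)
  back <- read_measurements(path)
  expect_equal(back, recs)

  bad <- recs
  names(bad)[3] <- "conc"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_measurements(path2), "concentration")

  zero <- recs
  zero$concentration[2] <- 0
  expect_error(validate_measurements(zero), "row\\(s\\): 2")
})

test_that("summarize_heg computes arithmetic and log-scale moments", {
  const <- summarize_heg(records_of(c(1, 1, 1)))
  expect_equal(const$am, 1)
  expect_equal(const$sd, 0)
  expect_equal(const$gm, 1)
  expect_equal(const$gsd, 1)

  st <- summarize_heg(records_of(c(1, 2, 4)))
  expect_equal(st$gm, 2, tolerance = 1e-12)
  expect_equal(st$gsd, 2, tolerance = 1e-12)
  expect_equal(st$am, 7 / 3, tolerance = 1e-12)
  expect_equal(st$sd, sd(c(1, 2, 4)), tolerance = 1e-12)
  expect_equal(st$ybar, log(2), tolerance = 1e-12)
  expect_equal(st$s_y, log(2), tolerance = 1e-12)

  expect_error(summarize_heg(records_of(1.5)), "at least 2")
  mixed <- rbind(records_of(c(1, 2)), records_of(3, heg_id = "Y"))
  expect_error(summarize_heg(mixed), "one HEG")
})

test_that("stats_from_table inverts printed GM/GSD summaries", {
  a <- stats_from_table(14, 1.52, 2.55)
  expect_equal(a$ybar, log(1.52), tolerance = 1e-12)
  expect_equal(a$s_y, log(2.55), tolerance = 1e-12)
  expect_equal(a$ybar, 0.41871, tolerance = 1e-4)
  expect_equal(a$s_y, 0.93609, tolerance = 1e-4)

  flat <- stats_from_table(10, 1.0, 1.0)
  expect_equal(flat$ybar, 0)
  expect_equal(flat$s_y, 0)

  d <- stats_from_table(52, 0.42, 3.29)
  expect_equal(d$ybar, -0.86750, tolerance = 1e-4)
  expect_equal(d$s_y, 1.19089, tolerance = 1e-4)

  expect_error(stats_from_table(10, 1.0, 0.9), "gsd")
})

test_that("log-scale and arithmetic summaries obey the AM-GM inequality", {
  for (seed in 1:20) {
    recs <- generate_heg(n = 5 + seed, gm = runif(1, 0.2, 3),
                         gsd = runif(1, 1, 4), seed = seed,
                         match_moments = FALSE)
    st <- summarize_heg(recs)
    expect_lte(st$gm, st$am + 1e-12)
    expect_equal(st$gm, exp(st$ybar), tolerance = 1e-12)
    expect_equal(st$gsd, exp(st$s_y), tolerance = 1e-12)
  }
})
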