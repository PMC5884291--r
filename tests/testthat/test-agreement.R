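test_that("Bland-Altman statistics match hand computation", {
  d <- tibble::tibble(a = c(10, 20, 30), b = c(11, 19, 31))
  ba <- bland_altman(d)
  expect_equal(ba$mean_diff, -1 / 3)
  expect_equal(ba$sd_diff, sd(c(-1, 1, -1)))
  expect_equal(ba$lower, -2.5965, tolerance = 1e-4)
  expect_equal(ba$upper, 1.9299, tolerance = 1e-4)
  expect_equal(ba$n_outside, 0)
  expect_equal(ba$fraction_within, 1)
  expect_equal(ba$data$pair_mean, c(10.5, 19.5, 30.5))

  # identical methods: limits collapse on zero, everything within
  same <- tibble::tibble(a = c(3, 1, 4, 1, 5), b = c(3, 1, 4, 1, 5))
  ba0 <- bland_altman(same)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(c(ba0$lower, ba0$upper), c(0, 0))
  expect_equal(ba0$fraction_within, 1)

  expect_error(bland_altman(tibble::tibble(a = 1, b = 2)), "at least 2")
})

test_that("swapping methods negates the bias; shifting b shifts the limits", {
  set.seed(81)
  d <- tibble::tibble(a = rnorm(40, 90, 5), b = rnorm(40, 89, 5))
  ab <- bland_altman(d, a, b)
  ba <- bland_altman(d, b, a)
  expect_equal(ba$mean_diff, -ab$mean_diff)
  expect_equal(ba$lower, -ab$upper)
  expect_equal(ba$upper, -ab$lower)
  expect_equal(ba$sd_diff, ab$sd_diff)

  cshift <- 2.5
  d2 <- dplyr::mutate(d, b = b + cshift)
  ab2 <- bland_altman(d2)
  expect_equal(ab2$mean_diff, ab$mean_diff - cshift)
  expect_equal(ab2$lower, ab$lower - cshift)
  expect_equal(ab2$upper, ab$upper - cshift)
  expect_equal(ab2$sd_diff, ab$sd_diff)
})

test_that("repeatability statistics follow the RMS definition", {
  d <- tibble::tibble(session1 = c(1, -1, 2, -2), session2 = c(0, 0, 0, 0))
  rp <- repeatability(d)
  expect_equal(rp$mean_u, 0)
  expect_equal(rp$cr, sqrt(10 / 4))
  # identical sessions: perfect repeatability
  same <- tibble::tibble(session1 = c(90, 91), session2 = c(90, 91))
  rp0 <- repeatability(same)
  expect_equal(rp0$mean_u, 0)
  expect_equal(rp0$cr, 0)
  expect_equal(rp0$cr_percent, 0)
  # percent convention against the protocol's nominal 90 degrees
  expect_equal(100 * 3.6406 / 90, 4.045, tolerance = 1e-3)

  expect_error(repeatability(same, reference = -1), "positive")
})

test_that("CR dominates the mean and decomposes into variance plus bias", {
  set.seed(91)
  for (i in 1:50) {
    n <- sample(3:60, 1)
    d <- tibble::tibble(session1 = rnorm(n, 90, 3), session2 = rnorm(n, 90, 3))
    rp <- repeatability(d)
    u <- d$session1 - d$session2
    expect_gte(rp$cr + 1e-12, abs(rp$mean_u))
    sd_pop2 <- mean((u - mean(u))^2)
    expect_equal(rp$cr^2, sd_pop2 + mean(u)^2, tolerance = 1e-10)
  }
})

test_that("difference-simulation recovers injected bias and spread", {
  set.seed(101)
  n <- 4000
  bias <- 1.7
  sigma <- 2.4
  a <- runif(n, 0, 180)
  d <- tibble::tibble(a = a, b = a + bias + rnorm(n, 0, sigma))
  ba <- bland_altman(d)
  expect_equal(ba$mean_diff, -bias, tolerance = 0.15)
  expect_equal((ba$upper - ba$lower) / 3.92, sigma, tolerance = 0.1)
  expect_equal(ba$fraction_within, 0.95, tolerance = 0.015)
})

test_that("tidy, glance and reports expose the documented fields", {
  d <- tibble::tibble(a = c(10, 20, 30), b = c(11, 19, 31))
  ba <- bland_altman(d)
  td <- tidy(ba)
  expect_equal(td$term[1:4], c("mean_diff", "sd_diff", "lower", "upper"))
  gl <- glance(ba)
  expect_equal(gl$n, 3)
  expect_named(gl, c("n", "mean_diff", "sd_diff", "lower", "upper",
                     "n_outside", "fraction_within"))

  rep <- agreement_report(ba)
  expect_true(all(c("n", "lower", "upper", "fraction_within") %in%
                    names(rep)))
  expect_length(rep$plot$pair_mean, 3)
  expect_false(any(vapply(rep, is.null, logical(1))))

  # JSON round trip is a fixed point
  f <- tempfile(fileext = ".json")
  write_report_json(rep, f)
  back <- read_report_json(f)
  f2 <- tempfile(fileext = ".json")
  write_report_json(back, f2)
  expect_identical(read_report_json(f2), back)
  expect_equal(back$mean_diff, ba$mean_diff)

  rp <- repeatability(tibble::tibble(session1 = c(91, 89, 92),
                                     session2 = c(90, 90, 90)))
  rrep <- agreement_report(rp)
  expect_true(all(c("cr", "cr_percent", "reference") %in% names(rrep)))
  expect_s3_class(glance(rp), "tbl_df")
})

test_that("plots build without error", {
  d <- tibble::tibble(a = rnorm(20, 90, 3), b = rnorm(20, 90, 3))
  ba <- bland_altman(d)
  expect_s3_class(autoplot(ba), "ggplot")
  rp <- repeatability(tibble::tibble(session1 = rnorm(10, 90, 2),
                                     session2 = rnorm(10, 90, 2)))
  expect_s3_class(autoplot(rp), "ggplot")
  ang <- angle_series(ramp_sequence(duration = 1))
  expect_s3_class(autoplot(ang), "ggplot")
  pre <- preprocess_sequence(ramp_sequence(duration = 1))
  expect_s3_class(plot_stages(pre, "right_wrist", "y"), "ggplot")
})
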