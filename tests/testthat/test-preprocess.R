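test_that("outlier replacement follows the threshold rule per policy", {
  # constant series: nothing to flag under any policy
  for (p in c("neighbors", "literal3", "global")) {
    res <- remove_outliers(rep(5, 5), policy = p)
    expect_equal(res$values, rep(5, 5))
    expect_no_flags(res)
  }
  # neighbours-only: spike neighbours are (0, 0) so L1 = L2 = 0 and the
  # spike is replaced by the neighbours' mean
  res <- remove_outliers(c(0, 0, 10, 0, 0), policy = "neighbors")
  expect_equal(res$values, c(0, 0, 0, 0, 0))
  expect_equal(res$windows$index, 3L)
  expect_equal(res$windows$lower, 0)
  expect_equal(res$windows$upper, 0)
  # literal 3-point window: max attainable |z| is 2/sqrt(3) < 1.96,
  # so even a huge spike is never flagged
  res3 <- remove_outliers(c(0, 0, 10, 0, 0), policy = "literal3")
  expect_equal(res3$values, c(0, 0, 10, 0, 0))
  expect_no_flags(res3)
  expect_equal(res3$values[3], 10)
  # hand values for the literal window around the spike
  w <- c(0, 10, 0)
  expect_equal(mean(w) + 1.96 * sqrt(sum((w - mean(w))^2) / 3),
               12.57, tolerance = 1e-3)

  expect_error(remove_outliers(c(1, 2)), "too short")
  # endpoints are never replaced
  res_end <- remove_outliers(c(100, 0, 0, 0, -100), policy = "global")
  expect_equal(res_end$values[c(1, 5)], c(100, -100))
})

test_that("block interpolation straightens interiors and is a projection", {
  expect_equal(interpolate_blocks(as.numeric(0:9)), as.numeric(0:9))
  expect_equal(interpolate_blocks(c(0, 5, -5, 2, 8, 1, 7, -3, 4, 9)),
               as.numeric(0:9))
  x7 <- c(3, 1, 4, 1, 5, 9, 2)
  expect_equal(interpolate_blocks(x7), x7)  # partial block passes through
  set.seed(21)
  for (len in c(10, 23, 40, 57)) {
    x <- rnorm(len)
    once <- interpolate_blocks(x)
    expect_equal(interpolate_blocks(once), once)  # idempotent
    expect_length(once, len)
  }
})

test_that("moving average matches windowed means and stays bounded", {
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 3), c(1.5, 2, 3, 4, 4.5))
  expect_equal(moving_average(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  expect_equal(moving_average(rep(2.7, 8), 5), rep(2.7, 8))
  expect_error(moving_average(1:5, 4), "odd")
  expect_error(moving_average(1:5, -1), "odd|positive")
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(5:80, 1))
    n <- sample(c(1, 3, 5, 7, 9), 1)
    y <- moving_average(x, n)
    expect_length(y, length(x))
    expect_true(all(y >= min(x) - 1e-12 & y <= max(x) + 1e-12))
  }
})

test_that("each stage matches its brute-force oracle on random series", {
  set.seed(41)
  for (i in 1:60) {
    len <- sample(3:100, 1)
    x <- rnorm(len)
    for (p in c("neighbors", "literal3", "global")) {
      expect_lt(max(abs(remove_outliers(x, p)$values -
                          oracle_remove_outliers(x, p))), 1e-12)
    }
    expect_lt(max(abs(interpolate_blocks(x) - oracle_interpolate_blocks(x))),
              1e-12)
    n <- sample(c(1, 3, 5, 9), 1)
    expect_lt(max(abs(moving_average(x, n) - oracle_moving_average(x, n))),
              1e-12)
  }
})

test_that("neighbours policy is idempotent on isolated spikes", {
  set.seed(51)
  x <- sin(seq(0, 4 * pi, length.out = 80)) + rnorm(80, 0, 0.01)
  spike_at <- c(10, 25, 61)
  x[spike_at] <- x[spike_at] + 15
  first <- remove_outliers(x, "neighbors")
  expect_true(all(spike_at %in% first$windows$index))
  second <- remove_outliers(first$values, "neighbors")
  expect_no_flags(second)
})

test_that("sequence cleaning preserves shape and touches only noisy joints", {
  skel <- ramp_sequence(duration = 4)
  pre <- preprocess_sequence(skel)
  expect_equal(nrow(pre), nrow(skel))
  expect_equal(pre$t, skel$t)
  expect_equal(pre$frame, skel$frame)
  # the neighbours rule may flag smooth-curve extrema (symmetric difference
  # vanishes there), but the replacement error stays negligible
  expect_lte(sum(attr(pre, "outlier_counts")$n_flagged), 5)
  st <- attr(pre, "stages")
  expect_lt(max(abs(st$deoutliered$x - skel$x)), 1e-3)
  # clean input is nearly a fixed point away from the series edges, where
  # the clipped smoothing window biases a trending coordinate
  interior <- skel$frame >= 2 & skel$frame <= max(skel$frame) - 2
  expect_lt(max(abs(pre$x[interior] - skel$x[interior])), 0.01)
  expect_lt(max(abs(pre$y[interior] - skel$y[interior])), 0.01)
  expect_lt(max(abs(pre$x - skel$x)), 0.05)

  # spike on one joint: all other joints bit-identical to the spike-free run
  spiked <- skel
  row <- which(spiked$joint == "right_wrist" & spiked$frame == 40)
  spiked$y[row] <- spiked$y[row] + 1
  pre_sp <- preprocess_sequence(spiked)
  others <- spiked$joint != "right_wrist"
  expect_identical(pre_sp$y[others], pre$y[others])
  expect_identical(pre_sp$x, pre$x)
  # and the spike itself is suppressed
  wr <- pre_sp$joint == "right_wrist"
  expect_lt(max(abs(pre_sp$y[wr] - pre$y[wr])), 0.05)

  expect_error(preprocess_sequence(skel[0, ]), "empty")
})

test_that("cleaning stages are retrievable in pipeline order", {
  skel <- ramp_sequence(duration = 2, noise = noise_config(0.01, 0.02,
                                                           seed = 7))
  pre <- preprocess_sequence(skel, keep_stages = TRUE)
  st <- attr(pre, "stages")
  expect_named(st, c("raw", "deoutliered", "interpolated", "smoothed"))
  expect_equal(st$raw$y, skel$y)
  expect_identical(st$smoothed$y, pre$y)
  pre2 <- preprocess_sequence(skel, keep_stages = FALSE)
  expect_null(attr(pre2, "stages"))
  expect_identical(pre2$y, pre$y)
})
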