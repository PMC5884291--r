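test_that("identical seeds give bit-identical sequences and tables", {
  n <- noise_config(0.02, 0.05, seed = 123)
  s1 <- simulate_movement(function(t) 30 * t, noise = n, duration = 2)
  s2 <- simulate_movement(function(t) 30 * t, noise = n, duration = 2)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))

  p1 <- protocol1_static(n_subjects = 2, seed = 7)
  p2 <- protocol1_static(n_subjects = 2, seed = 7)
  expect_identical(p1, p2)
  q1 <- protocol2_sessions(n_subjects = 3, seed = 9)
  q2 <- protocol2_sessions(n_subjects = 3, seed = 9)
  expect_identical(q1, q2)

  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_skeleton_csv(s1, f1)
  write_skeleton_csv(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a noiseless static pose yields identical frames at the true angle", {
  skel <- simulate_movement(90, noise = silent_noise(), duration = 1)
  expect_equal(length(unique(skel$frame)), 30)
  first <- skel[skel$frame == 0, c("joint", "x", "y", "z")]
  for (f in unique(skel$frame)) {
    expect_identical(skel[skel$frame == f, c("joint", "x", "y", "z")], first)
  }
  ang <- angle_series(skel, "shoulder_abduction", "right", "coronal")
  expect_equal(ang$theta_deg, rep(90, 30))
})

test_that("single-frame angular noise follows the error-propagation scale", {
  # shoulder-to-wrist 0.60 m, per-coordinate noise 0.02 m on both endpoints:
  # transverse direction error sd ~ 0.02 * sqrt(2) / 0.60 rad = 2.70 deg
  arm <- arm_model(upper_arm = 0.30, forearm = 0.30)
  skel <- simulate_movement(90, arm = arm,
                            noise = noise_config(0.02, 0, seed = 31),
                            fps = 30, duration = 100)
  frames <- sort(unique(skel$frame))
  sh <- kinagree:::.joint_matrix(skel, "right_shoulder", frames)
  wr <- kinagree:::.joint_matrix(skel, "right_wrist", frames)
  v <- wr - sh
  down <- matrix(rep(c(0, -1, 0), each = nrow(v)), ncol = 3)
  theta <- kinagree:::.angle_rows(v, down)
  predicted <- 0.02 * sqrt(2) / 0.60 * 180 / pi
  expect_equal(sd(theta), predicted, tolerance = 0.2 * predicted)
})

test_that("doubling position noise doubles the angular error", {
  arm <- arm_model(upper_arm = 0.30, forearm = 0.30)
  err_sd <- function(sd_pos, seed) {
    skel <- simulate_movement(90, arm = arm,
                              noise = noise_config(sd_pos, 0, seed = seed),
                              fps = 30, duration = 70)
    frames <- sort(unique(skel$frame))
    v <- kinagree:::.joint_matrix(skel, "right_wrist", frames) -
      kinagree:::.joint_matrix(skel, "right_shoulder", frames)
    down <- matrix(rep(c(0, -1, 0), each = nrow(v)), ncol = 3)
    sd(kinagree:::.angle_rows(v, down))
  }
  ratio <- err_sd(0.02, 41) / err_sd(0.01, 42)
  expect_gte(ratio, 1.8)
  expect_lte(ratio, 2.2)
})

test_that("protocol 1 has the counting contract and is exact when noiseless", {
  p <- protocol1_static(n_subjects = 9, seed = 11)
  expect_equal(nrow(p), 9 * 19 * 2)
  expect_equal(sort(unique(p$angle_deg)), seq(0, 180, 10))

  # perfect instruments: goniometer and pipeline agree up to quantisation
  p0 <- protocol1_static(
    noise = silent_noise(),
    goniometer = goniometer_model(observer_bias = 0, observer_sd = 0),
    n_subjects = 1, seed = 12
  )
  expect_lte(max(abs(p0$a - p0$b)), 0.5 + 1e-9)
  ba <- bland_altman(p0)
  expect_equal(ba$mean_diff, 0, tolerance = 0.5)
  # limits collapse to zero width up to floating-point residue; comparing at
  # the instrument resolution, every pair agrees
  expect_lt(ba$upper - ba$lower, 1e-6)
  quantised <- dplyr::mutate(p0, b = round(b))
  expect_equal(bland_altman(quantised)$fraction_within, 1)
})

test_that("protocol 2 is perfectly repeatable when all noise is off", {
  q <- protocol2_sessions(noise = silent_noise(), session_sd = 0,
                          n_subjects = 3, seed = 13)
  rp <- repeatability(q)
  expect_equal(rp$cr, 0, tolerance = 1e-9)
  expect_equal(q$session1, rep(90, 3), tolerance = 1e-6)
  # axial variant holds the arm at 90 degrees elevation too
  qa <- protocol2_sessions(noise = silent_noise(), session_sd = 0,
                           n_subjects = 2, plane = "axial", seed = 14)
  expect_equal(qa$session1, rep(90, 2), tolerance = 1e-6)
})

test_that("injected observer bias propagates to the agreement bias", {
  p <- protocol1_static(
    noise = noise_config(0.01, 0),
    goniometer = goniometer_model(observer_bias = -0.46, observer_sd = 1),
    n_subjects = 4, seed = 15
  )
  ba <- bland_altman(p)
  expect_equal(ba$mean_diff, -0.46, tolerance = 0.5)
})
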