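# Synthetic data: a rigid forward-kinematic arm model with depth-sensor
# noise, a goniometer observer model, and generators for the two validation
# protocols (static abduction ladder; two-session 90-degree flexion).
#
# Pose conventions (documented, since only clinical movement names exist in
# the field description): the subject stands 2 m from the sensor facing it,
# so the subject's right side appears at negative camera x.  An arm hanging
# at the side is 0 degrees; abduction rotates the straight arm away from the
# trunk within the coronal plane, flexion raises it forward (toward the
# sensor) in the sagittal plane.  The axial variant keeps the arm elevated at
# 90 degrees and sweeps its azimuth from straight-ahead toward lateral.

#' Rigid arm model
#'
#' Segment lengths are scaled from subject stature with standard
#' anthropometric fractions (trunk 0.288 H, half-biacromial shoulder offset
#' 0.129 H, upper arm 0.186 H, forearm 0.146 H, hand 0.108 H).  The default
#' stature 1.69 m matches the study cohort; any length can be overridden.
#'
#' @param height Subject stature in metres.
#' @param trunk,shoulder_offset,upper_arm,forearm,hand Optional explicit
#'   segment lengths in metres (override the stature scaling).
#' @return An `arm_model` list of segment lengths.
#' @export
arm_model <- function(height = 1.69, trunk = NULL, shoulder_offset = NULL,
                      upper_arm = NULL, forearm = NULL, hand = NULL) {
  m <- list(
    height = height,
    trunk = trunk %||% (0.288 * height),
    shoulder_offset = shoulder_offset %||% (0.129 * height),
    upper_arm = upper_arm %||% (0.186 * height),
    forearm = forearm %||% (0.146 * height),
    hand = hand %||% (0.108 * height)
  )
  if (any(unlist(m) <= 0)) abort("all arm-model lengths must be positive")
  structure(m, class = "arm_model")
}

#' Depth-sensor noise model
#'
#' Isotropic Gaussian position noise added to every joint coordinate, plus
#' sporadic isolated outliers: with probability `outlier_rate` per joint per
#' frame the position is displaced by `outlier_scale * position_sd` in a
#' random direction (emulating single-frame joint-inference failures).  The
#' default `position_sd` of 0.0245 m sits midway in the sensor's reported
#' 14.1-34.8 mm error range.
#'
#' @param position_sd Per-coordinate noise sd, metres.
#' @param outlier_rate Outlier probability per joint-sample, in \[0, 1\].
#' @param outlier_scale Outlier displacement as a multiple of `position_sd`.
#' @param seed Optional integer seed recorded in output metadata.
#' @return A `noise_config` list.
#' @export
noise_config <- function(position_sd = 0.0245, outlier_rate = 0.01,
                         outlier_scale = 10, seed = NULL) {
  if (position_sd < 0) abort("`position_sd` must be non-negative")
  if (outlier_rate < 0 || outlier_rate > 1) {
    abort("`outlier_rate` must be in [0, 1]")
  }
  structure(
    list(position_sd = position_sd, outlier_rate = outlier_rate,
         outlier_scale = outlier_scale, seed = seed),
    class = "noise_config"
  )
}

#' Goniometer observer model
#'
#' A manual goniometer reading of a true angle: true value plus a systematic
#' observer bias, plus Gaussian observer noise, rounded to the instrument
#' resolution (whole degrees by default; `quantization = 0` disables
#' rounding).
#'
#' @param observer_bias Systematic reading bias, degrees.
#' @param observer_sd Observer noise sd, degrees.
#' @param quantization Instrument resolution, degrees (0 = none).
#' @return A `goniometer_model` list.
#' @export
goniometer_model <- function(observer_bias = 0, observer_sd = 1,
                             quantization = 1) {
  if (quantization < 0) abort("`quantization` must be non-negative")
  if (observer_sd < 0) abort("`observer_sd` must be non-negative")
  structure(
    list(observer_bias = observer_bias, observer_sd = observer_sd,
         quantization = quantization),
    class = "goniometer_model"
  )
}

.gonio_read <- function(theta, g) {
  r <- theta + g$observer_bias + rnorm(length(theta), 0, g$observer_sd)
  if (g$quantization > 0) r <- round(r / g$quantization) * g$quantization
  r
}

# In-plane arm direction unit vectors for a vector of angles (radians).
# sign is the lateral x direction of the moving side (-1 right, +1 left).
.arm_direction <- function(theta_rad, plane, sign) {
  ct <- cos(theta_rad)
  st <- sin(theta_rad)
  z <- numeric(length(theta_rad))
  switch(plane,
    coronal  = cbind(sign * st, -ct, z),
    sagittal = cbind(z, -ct, -st),
    # axial: arm elevated 90 deg; theta sweeps azimuth from forward (-z)
    # toward lateral
    axial    = cbind(sign * st, z, -ct)
  )
}

# Noise-free joint positions for a vector of commanded angles (degrees).
# Returns a named list of T x 3 matrices, in emission order.
.fk_positions <- function(theta_deg, plane, side, arm,
                          joints = c("upper", "minimal")) {
  joints <- match.arg(joints)
  nT <- length(theta_deg)
  sgn <- if (side == "right") -1 else 1
  rep_row <- function(p) matrix(p, nrow = nT, ncol = 3, byrow = TRUE)
  z0 <- 2                                 # recommended sensor distance, m
  hip <- c(0, 0, z0)
  sc <- hip + c(0, arm$trunk, 0)
  pos <- list(hip_center = rep_row(hip))
  if (joints == "upper") {
    pos$spine <- rep_row(hip + c(0, arm$trunk / 2, 0))
  }
  pos$shoulder_center <- rep_row(sc)
  if (joints == "upper") {
    pos$head <- rep_row(sc + c(0, 0.1 * arm$height, 0))
  }
  sides <- if (joints == "upper") c("left", "right") else side
  dir_down <- cbind(numeric(nT), rep(-1, nT), numeric(nT))
  for (s in sides) {
    ssgn <- if (s == "right") -1 else 1
    sh <- sc + c(ssgn * arm$shoulder_offset, 0, 0)
    shm <- rep_row(sh)
    dir <- if (s == side) {
      .arm_direction(theta_deg * pi / 180, plane, sgn)
    } else {
      dir_down
    }
    el <- shm + arm$upper_arm * dir
    wr <- el + arm$forearm * dir
    ha <- wr + arm$hand * dir
    pos[[paste0(s, "_shoulder")]] <- shm
    pos[[paste0(s, "_elbow")]] <- el
    pos[[paste0(s, "_wrist")]] <- wr
    pos[[paste0(s, "_hand")]] <- ha
  }
  pos
}

#' Simulate a noisy skeleton sequence from a commanded movement
#'
#' Rigid forward kinematics (shoulder pivot, straight elbow) drive one arm
#' through a commanded angle-versus-time profile in a given anatomical
#' plane, sampled at `fps`.  Isotropic Gaussian noise of sd `position_sd` is
#' added to every joint coordinate, and with probability `outlier_rate` a
#' joint sample is displaced by `outlier_scale * position_sd` in a random
#' direction.  Identical seeds give bit-identical output.
#'
#' @param profile Commanded angle in degrees: a single number (static pose)
#'   or a function of time in seconds returning degrees.
#' @param plane Movement plane: `"coronal"`, `"sagittal"` or `"axial"`.
#' @param side Moving arm, `"right"` or `"left"`.
#' @param arm An [arm_model()].
#' @param noise A [noise_config()].
#' @param fps Sampling rate, frames per second.
#' @param duration Recording length, seconds.
#' @param joints `"upper"` (full upper-body joint set) or `"minimal"` (only
#'   the joints the moving side's angle computation needs).
#' @param seed Integer seed; defaults to `noise$seed`.  `NULL` leaves the
#'   random-number stream untouched.
#' @return A `skeleton_sequence` with the generating configuration in its
#'   `config` attribute.
#' @examples
#' skel <- simulate_movement(90, noise = noise_config(0, 0, seed = 1),
#'                           duration = 1)
#' @export
simulate_movement <- function(profile, plane = "coronal",
                              side = c("right", "left"),
                              arm = arm_model(), noise = noise_config(),
                              fps = 30, duration = 2,
                              joints = c("upper", "minimal"),
                              seed = noise$seed) {
  side <- match.arg(side)
  joints <- match.arg(joints)
  plane <- match.arg(plane, names(.PLANES))
  if (fps <= 0 || duration <= 0) abort("`fps` and `duration` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  nT <- as.integer(round(fps * duration))
  if (nT < 1L) abort("duration too short for one frame")
  tt <- (seq_len(nT) - 1L) / fps
  theta <- if (is.function(profile)) profile(tt) else rep(profile, nT)
  if (length(theta) != nT || !all(is.finite(theta))) {
    abort("profile must yield one finite angle per frame")
  }
  pos <- .fk_positions(theta, plane, side, arm, joints)
  sdp <- noise$position_sd
  for (j in names(pos)) {
    if (sdp > 0) {
      pos[[j]] <- pos[[j]] + matrix(rnorm(3L * nT, 0, sdp), ncol = 3L)
    }
    if (noise$outlier_rate > 0) {
      hit <- which(runif(nT) < noise$outlier_rate)
      if (length(hit) > 0L) {
        dirs <- matrix(rnorm(3L * length(hit)), ncol = 3L)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        pos[[j]][hit, ] <- pos[[j]][hit, , drop = FALSE] +
          noise$outlier_scale * sdp * dirs
      }
    }
  }
  nj <- length(pos)
  jnames <- names(pos)
  # frame-major long form: one row per joint per frame
  xs <- matrix(NA_real_, nrow = nj, ncol = nT)
  ys <- xs
  zs <- xs
  for (k in seq_len(nj)) {
    xs[k, ] <- pos[[k]][, 1]
    ys[k, ] <- pos[[k]][, 2]
    zs[k, ] <- pos[[k]][, 3]
  }
  cfg <- list(
    profile = if (is.function(profile)) "function" else profile,
    plane = plane, side = side, fps = fps, duration = duration,
    joints = joints, position_sd = sdp,
    outlier_rate = noise$outlier_rate, outlier_scale = noise$outlier_scale,
    seed = seed
  )
  new_skeleton_sequence(
    list(
      frame = rep(0:(nT - 1L), each = nj),
      t = rep(tt, each = nj),
      joint = rep(jnames, times = nT),
      x = as.vector(xs), y = as.vector(ys), z = as.vector(zs)
    ),
    nominal_rate = fps, config = cfg
  )
}

# Full measurement-pipeline estimate of a static commanded angle: simulate a
# short burst, clean it, compute the angle series, take the median.
.burst_estimate <- function(theta, side, plane, articulation, arm, noise,
                            frames = 30L, policy = "neighbors",
                            window_n = 5L) {
  skel <- simulate_movement(
    theta, plane = plane, side = side, arm = arm, noise = noise,
    fps = 30, duration = frames / 30, joints = "minimal", seed = NULL
  )
  pre <- preprocess_sequence(skel, policy = policy, window_n = window_n,
                             keep_stages = FALSE)
  ang_plane <- if (plane == "axial") "3D" else plane
  ang <- angle_series(pre, articulation = articulation, side = side,
                      plane = ang_plane)
  median(ang$theta_deg, na.rm = TRUE)
}

#' Protocol 1: static goniometer-versus-pipeline comparison
#'
#' Emulates the static agreement experiment: each subject holds the arm at
#' every commanded abduction angle (default every 10 degrees from 0 to 180,
#' both arms) while the angle is read twice — method A by the goniometer
#' observer model, method B by the full measurement pipeline (noisy static
#' burst, cleaning, coronal-plane angle series, median over frames).
#'
#' @param arm An [arm_model()].
#' @param noise A [noise_config()] for the sensor.
#' @param goniometer A [goniometer_model()] for the human observer.
#' @param step Commanded-angle step, degrees; must divide the range.
#' @param range Commanded-angle range `c(lo, hi)`, degrees.
#' @param n_subjects Number of simulated subjects.
#' @param sides Arms measured per subject.
#' @param frames Frames per static burst (default 30, i.e. 1 s).
#' @param policy,window_n Cleaning settings, see [preprocess_sequence()].
#' @param seed Integer seed for the whole protocol (the seed inside `noise`
#'   is ignored here so each burst draws fresh noise).
#' @return A tibble with columns `subject`, `side`, `angle_deg`, `a`
#'   (goniometer, degrees), `b` (pipeline, degrees), ready for
#'   [bland_altman()].
#' @export
protocol1_static <- function(arm = arm_model(), noise = noise_config(),
                             goniometer = goniometer_model(),
                             step = 10, range = c(0, 180), n_subjects = 9,
                             sides = c("left", "right"), frames = 30L,
                             policy = "neighbors", window_n = 5L,
                             seed = NULL) {
  if (step <= 0 || (range[2] - range[1]) %% step != 0) {
    abort("`step` must be positive and divide the angle range")
  }
  if (!is.null(seed)) set.seed(seed)
  angles <- seq(range[1], range[2], by = step)
  n <- n_subjects * length(sides) * length(angles)
  subject <- character(n)
  side_v <- character(n)
  angle_v <- numeric(n)
  a <- numeric(n)
  b <- numeric(n)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (sd_ in sides) {
      for (th in angles) {
        k <- k + 1L
        subject[k] <- sid
        side_v[k] <- sd_
        angle_v[k] <- th
        a[k] <- .gonio_read(th, goniometer)
        b[k] <- .burst_estimate(th, sd_, "coronal", "shoulder_abduction",
                                arm, noise, frames, policy, window_n)
      }
    }
  }
  out <- tibble(subject = subject, side = side_v, angle_deg = angle_v,
                a = a, b = b)
  attr(out, "config") <- list(
    protocol = 1, step = step, range = range, n_subjects = n_subjects,
    sides = sides, frames = frames, policy = policy, window_n = window_n,
    position_sd = noise$position_sd, outlier_rate = noise$outlier_rate,
    observer_bias = goniometer$observer_bias,
    observer_sd = goniometer$observer_sd,
    quantization = goniometer$quantization, seed = seed
  )
  out
}

#' Protocol 2: two-session repeatability of a 90-degree flexion
#'
#' Emulates the repeatability experiment: every subject performs the same
#' 90-degree shoulder flexion in two separate sessions, and each session's
#' pipeline estimate is additionally perturbed by session-level Gaussian
#' variation (set-up, posture and lighting differences between visits).
#' The default `session_sd` is calibrated so the between-session difference
#' `u` has sd 3.204 degrees, reproducing a repeatability interval of about
#' +/- 6.28 degrees.
#'
#' @param arm An [arm_model()].
#' @param noise A [noise_config()] for the sensor.
#' @param session_sd Between-session sd per session, degrees.
#' @param n_subjects Number of simulated subjects (>= 2).
#' @param target Commanded flexion angle, degrees.
#' @param plane `"sagittal"` (default) or `"axial"` movement variant.
#' @param frames,policy,window_n Burst and cleaning settings.
#' @param seed Integer seed for the whole protocol.
#' @return A tibble with columns `subject`, `session1`, `session2`
#'   (degrees), ready for [repeatability()].
#' @export
protocol2_sessions <- function(arm = arm_model(), noise = noise_config(),
                               session_sd = 3.204 / sqrt(2),
                               n_subjects = 9, target = 90,
                               plane = c("sagittal", "axial"),
                               frames = 30L, policy = "neighbors",
                               window_n = 5L, seed = NULL) {
  plane <- match.arg(plane)
  if (n_subjects < 2) abort("`n_subjects` must be at least 2")
  if (session_sd < 0) abort("`session_sd` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  s1 <- numeric(n_subjects)
  s2 <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    s1[s] <- .burst_estimate(target, "right", plane, "shoulder_flexion",
                             arm, noise, frames, policy, window_n) +
      rnorm(1, 0, session_sd)
    s2[s] <- .burst_estimate(target, "right", plane, "shoulder_flexion",
                             arm, noise, frames, policy, window_n) +
      rnorm(1, 0, session_sd)
  }
  out <- tibble(subject = sprintf("S%04d", seq_len(n_subjects)),
                session1 = s1, session2 = s2)
  attr(out, "config") <- list(
    protocol = 2, session_sd = session_sd, n_subjects = n_subjects,
    target = target, plane = plane, frames = frames, policy = policy,
    window_n = window_n, position_sd = noise$position_sd,
    outlier_rate = noise$outlier_rate, seed = seed
  )
  out
}
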