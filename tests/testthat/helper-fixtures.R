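# Shared fixtures, built in code.

silent_noise <- function(seed = NULL) {
  noise_config(position_sd = 0, outlier_rate = 0, seed = seed)
}

# A complete single standing frame with the right arm abducted at `theta`
# degrees in the coronal plane, upper-limb joints only.
static_frame <- function(theta = 90) {
  skel <- simulate_movement(theta, plane = "coronal", side = "right",
                            noise = silent_noise(), fps = 30,
                            duration = 1 / 30)
  skel[skel$frame == 0, ]
}

# Noiseless abduction ramp 0 -> 180 degrees over `duration` seconds.
ramp_sequence <- function(duration = 6, noise = silent_noise(), seed = NULL) {
  simulate_movement(
    function(t) 180 * t / duration,
    plane = "coronal", side = "right", noise = noise,
    fps = 30, duration = duration, seed = seed
  )
}

expect_no_flags <- function(res) {
  expect_identical(res$n_flagged, 0L)
  expect_identical(nrow(res$windows), 0L)
}
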