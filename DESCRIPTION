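Package: kinagree
Title: Upper-Limb Joint Kinematics from Depth-Sensor Skeletons with
    Agreement and Repeatability Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cleaning 3D skeleton-joint trajectories recorded by a
    consumer depth sensor, computing clinical upper-limb joint angles, and
    statistically validating an optical motion-measurement method against
    manual goniometry.  Trajectory cleaning follows a three-stage pipeline
    (local outlier replacement, block-wise linear interpolation, centred
    moving-average smoothing) applied per joint and per coordinate.  Method
    validation uses Bland-Altman limits of agreement and the coefficient of
    repeatability.  A forward-kinematic arm simulator with sensor-noise and
    goniometer-observer models reproduces the static-pose and two-session
    experimental protocols end to end, so the whole pipeline is testable
    without hardware or human subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
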