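# Skeleton model: joint registries, camera-frame conventions, anatomical
# planes, and the body-segment chain used for all angle computations.
#
# Camera frame (Kinect v1 convention, fixed): x to the camera's right, y up,
# z away from the sensor along the depth axis.  Units are fixed package-wide:
# metres for positions, seconds for time, degrees for angles.

.KINECT_STANDING <- c(
  "hip_center", "spine", "shoulder_center", "head",
  "left_shoulder", "left_elbow", "left_wrist", "left_hand",
  "right_shoulder", "right_elbow", "right_wrist", "right_hand",
  "left_hip", "left_knee", "left_ankle", "left_foot",
  "right_hip", "right_knee", "right_ankle", "right_foot"
)

.KINECT_SEATED <- c(
  "head", "shoulder_center",
  "left_shoulder", "left_elbow", "left_wrist", "left_hand",
  "right_shoulder", "right_elbow", "right_wrist", "right_hand"
)

.PLANES <- list(
  coronal  = list(keep = c("x", "y"), dropped_axis = "z"),
  sagittal = list(keep = c("y", "z"), dropped_axis = "x"),
  axial    = list(keep = c("x", "z"), dropped_axis = "y")
)

#' Joint registry of the depth-sensor skeleton
#'
#' The standing skeleton carries 20 labelled joints, the seated skeleton the
#' 10 upper-body joints (head, shoulder centre, and shoulder/elbow/wrist/hand
#' on each side).  The upper-limb subset is present in both registries, so
#' every upper-limb operation applies unchanged to seated recordings; the
#' trunk segment additionally needs `hip_center` and is therefore only
#' available from standing frames.
#'
#' @param posture `"standing"` (20 joints) or `"seated"` (10 joints).
#' @return A tibble with columns `joint` (lower-snake-case label) and
#'   `posture`.
#' @examples
#' joint_registry()
#' joint_registry("seated")
#' @export
joint_registry <- function(posture = c("standing", "seated")) {
  posture <- match.arg(posture)
  labels <- if (posture == "standing") .KINECT_STANDING else .KINECT_SEATED
  tibble(joint = labels, posture = posture)
}

#' Anatomical plane registry
#'
#' Each plane is a projection of the camera frame obtained by discarding one
#' axis: coronal keeps (x, y), sagittal keeps (y, z), axial keeps (x, z).
#'
#' @return A tibble with columns `plane`, `keep_1`, `keep_2`, `dropped_axis`.
#' @export
anatomical_planes <- function() {
  tibble(
    plane = names(.PLANES),
    keep_1 = vapply(.PLANES, function(p) p$keep[1], character(1)),
    keep_2 = vapply(.PLANES, function(p) p$keep[2], character(1)),
    dropped_axis = vapply(.PLANES, function(p) p$dropped_axis, character(1))
  )
}

#' Project a 3-vector onto an anatomical plane
#'
#' Drops the plane's discarded camera axis and returns the two retained
#' coordinates in fixed (registry) order.
#'
#' @param v Numeric 3-vector in camera coordinates (x, y, z), metres.
#' @param plane `"coronal"`, `"sagittal"` or `"axial"`.
#' @return Numeric 2-vector.
#' @examples
#' project(c(1, 2, 3), "coronal")  # (1, 2)
#' project(c(1, 2, 3), "sagittal") # (2, 3)
#' @export
project <- function(v, plane) {
  plane <- match.arg(plane, names(.PLANES))
  if (!is.numeric(v) || length(v) != 3L) {
    abort("`v` must be a numeric 3-vector")
  }
  idx <- match(.PLANES[[plane]]$keep, c("x", "y", "z"))
  unname(v[idx])
}

#' Body-segment registry for one side
#'
#' The segment chain runs trunk -> shoulder-line -> arm -> forearm -> hand:
#' trunk = hip_center to shoulder_center, shoulder-line = shoulder_center to
#' the side's shoulder, arm = shoulder to elbow, forearm = elbow to wrist,
#' hand = wrist to hand.
#'
#' @param side `"right"` or `"left"`.
#' @return A tibble with columns `segment`, `origin_joint`, `tip_joint`.
#' @export
segment_registry <- function(side = c("right", "left")) {
  side <- match.arg(side)
  tibble(
    segment = c("trunk", "shoulder_line", "arm", "forearm", "hand"),
    origin_joint = c(
      "hip_center", "shoulder_center",
      paste0(side, "_shoulder"), paste0(side, "_elbow"),
      paste0(side, "_wrist")
    ),
    tip_joint = c(
      "shoulder_center", paste0(side, "_shoulder"),
      paste0(side, "_elbow"), paste0(side, "_wrist"),
      paste0(side, "_hand")
    )
  )
}

#' Segment vectors of a single frame
#'
#' Builds the five body-segment vectors (tip minus origin position, metres)
#' of one side from a single skeleton frame.  Segment vectors are
#' translation-invariant by construction, and chaining them from the hip
#' centre reproduces `position(hand) - position(hip_center)` exactly.
#'
#' @param frame A data frame with one row per joint and columns `joint`,
#'   `x`, `y`, `z` (a single-frame slice of a skeleton sequence).
#' @param side `"right"` or `"left"`.
#' @return A tibble with columns `segment`, `origin_joint`, `tip_joint`,
#'   `vx`, `vy`, `vz`.
#' @examples
#' f <- tibble::tibble(
#'   joint = c("hip_center", "shoulder_center", "right_shoulder",
#'             "right_elbow", "right_wrist", "right_hand"),
#'   x = 0, y = c(0, 0.5, 0.5, 0.2, -0.05, -0.15), z = 2
#' )
#' segment_vectors(f, "right")
#' @export
segment_vectors <- function(frame, side = c("right", "left")) {
  side <- match.arg(side)
  reg <- segment_registry(side)
  needed <- unique(c(reg$origin_joint, reg$tip_joint))
  miss <- setdiff(needed, frame$joint)
  if (length(miss) > 0L) {
    abort(sprintf("incomplete frame: missing joint '%s'", miss[1]),
          class = "kinagree_data_error")
  }
  at <- match(reg$origin_joint, frame$joint)
  bt <- match(reg$tip_joint, frame$joint)
  tibble(
    segment = reg$segment,
    origin_joint = reg$origin_joint,
    tip_joint = reg$tip_joint,
    vx = frame$x[bt] - frame$x[at],
    vy = frame$y[bt] - frame$y[at],
    vz = frame$z[bt] - frame$z[at]
  )
}

# -- skeleton sequence container ---------------------------------------------

new_skeleton_sequence <- function(data, nominal_rate = 30, config = NULL) {
  tibble::new_tibble(
    data,
    nrow = length(data[[1]]),
    nominal_rate = nominal_rate,
    config = config,
    class = "skeleton_sequence"
  )
}

#' Construct a skeleton sequence
#'
#' A skeleton sequence is a long-form tibble — one row per joint per frame —
#' with columns `frame` (0-based integer), `t` (seconds), `joint` (registry
#' label), `x`, `y`, `z` (metres, camera frame), and a `nominal_rate`
#' attribute (frames per second, default 30).  All pipeline stages consume
#' and produce this shape.
#'
#' @param data Data frame with columns `frame`, `t`, `joint`, `x`, `y`, `z`.
#' @param nominal_rate Nominal acquisition rate in frames per second (> 0).
#' @param validate Check invariants (finite coordinates, one position per
#'   joint per frame, strictly increasing `t` across frames)?
#' @return A `skeleton_sequence` tibble.
#' @export
skeleton_sequence <- function(data, nominal_rate = 30, validate = TRUE) {
  cols <- c("frame", "t", "joint", "x", "y", "z")
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0L) {
    abort(paste0("missing skeleton columns: ", paste(miss, collapse = ", ")),
          class = "kinagree_data_error")
  }
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1L ||
      nominal_rate <= 0) {
    abort("`nominal_rate` must be a single positive number")
  }
  data <- as_tibble(data)[cols]
  if (validate && nrow(data) > 0L) {
    for (cc in c("t", "x", "y", "z")) {
      bad <- which(!is.finite(data[[cc]]))
      if (length(bad) > 0L) {
        abort(sprintf("non-finite '%s' at row %d", cc, bad[1]),
              class = "kinagree_data_error")
      }
    }
    if (any(data$t < 0)) {
      abort("negative timestamps are not allowed",
            class = "kinagree_data_error")
    }
    if (anyDuplicated(data[c("frame", "joint")]) > 0L) {
      abort("duplicated joint within a frame", class = "kinagree_data_error")
    }
    ft <- unique(data[c("frame", "t")])
    if (anyDuplicated(ft$frame) > 0L) {
      abort("inconsistent `t` within a frame", class = "kinagree_data_error")
    }
    ft <- ft[order(ft$frame), ]
    if (nrow(ft) > 1L && any(diff(ft$t) <= 0)) {
      abort("`t` must be strictly increasing across frames",
            class = "kinagree_data_error")
    }
  }
  new_skeleton_sequence(data, nominal_rate = nominal_rate)
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  nf <- length(unique(x$frame))
  cat(sprintf(
    "<skeleton_sequence> %d frames x %d joints @ %g fps nominal\n",
    nf, length(unique(x$joint)), attr(x, "nominal_rate") %||% NA_real_
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Extract a frames x 3 coordinate matrix for one joint, rows ordered by
# frame.  `frames` is the sorted unique frame index of the sequence.
.joint_matrix <- function(seq, joint, frames) {
  rows <- which(seq$joint == joint)
  if (length(rows) != length(frames)) {
    abort(sprintf("incomplete frame: missing joint '%s'", joint),
          class = "kinagree_data_error")
  }
  rows <- rows[order(seq$frame[rows])]
  cbind(x = seq$x[rows], y = seq$y[rows], z = seq$z[rows])
}
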