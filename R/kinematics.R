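# Joint-angle kinematics: included angle between adjacent body segments,
# per-frame angle series (3D or projected onto an anatomical plane), and
# end-effector trajectory summaries (range of motion, path length, covered
# area).

#' Angle between two segment vectors
#'
#' Classical included angle: `acos` of the normalised inner product, in
#' degrees, in \[0, 180\].  The normalised product is clamped to \[-1, 1\]
#' before `acos` so floating-point round-off never produces `NaN`.  The
#' result is symmetric in its arguments and invariant to positive rescaling
#' of either one.
#'
#' @param p1,p2 Numeric 2- or 3-vectors (both of the same length).
#' @param eps Degeneracy threshold on the vector norms, metres
#'   (default 1e-9).
#' @return Angle in degrees.
#' @examples
#' joint_angle(c(1, 0, 0), c(0, 1, 0))  # 90
#' joint_angle(c(1, 0, 0), c(1, 1, 0))  # 45
#' @export
joint_angle <- function(p1, p2, eps = 1e-9) {
  if (!is.numeric(p1) || !is.numeric(p2) ||
      !length(p1) %in% c(2L, 3L) || length(p2) != length(p1)) {
    abort("`p1` and `p2` must be numeric 2- or 3-vectors of equal length")
  }
  n1 <- sqrt(sum(p1^2))
  n2 <- sqrt(sum(p2^2))
  if (n1 <= eps) {
    abort("degenerate segment: `p1` has near-zero length",
          class = "kinagree_data_error")
  }
  if (n2 <= eps) {
    abort("degenerate segment: `p2` has near-zero length",
          class = "kinagree_data_error")
  }
  acos(min(1, max(-1, sum(p1 * p2) / (n1 * n2)))) * 180 / pi
}

# Row-wise angle between two matrices of vectors; degenerate rows -> NA.
.angle_rows <- function(v1, v2, eps = 1e-9) {
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  num <- rowSums(v1 * v2)
  theta <- acos(pmin(1, pmax(-1, num / (n1 * n2)))) * 180 / pi
  theta[n1 <= eps | n2 <= eps] <- NA_real_
  theta
}

# Articulation registry: each clinical angle is the included angle between a
# reference vector and a segment vector, both defined as joint pairs
# (origin -> tip).  "{side}" is substituted at evaluation time.
# shoulder angles use the trunk-down reference (shoulder_center -> hip_center)
# so that an arm hanging at the side reads 0 degrees.
.ARTICULATIONS <- list(
  shoulder_abduction = list(
    ref = c("shoulder_center", "hip_center"),
    seg = c("{side}_shoulder", "{side}_elbow"),
    description = "arm elevation from the trunk-down reference (coronal-plane movement)"
  ),
  shoulder_flexion = list(
    ref = c("shoulder_center", "hip_center"),
    seg = c("{side}_shoulder", "{side}_elbow"),
    description = "arm elevation from the trunk-down reference (sagittal-plane movement)"
  ),
  elbow_flexion = list(
    ref = c("{side}_shoulder", "{side}_elbow"),
    seg = c("{side}_elbow", "{side}_wrist"),
    description = "angle between arm and forearm segments; 0 = straight arm"
  ),
  wrist_flexion = list(
    ref = c("{side}_elbow", "{side}_wrist"),
    seg = c("{side}_wrist", "{side}_hand"),
    description = "angle between forearm and hand segments; 0 = neutral"
  )
)

#' Articulation registry
#'
#' Lists the clinical angles the package computes.  Each articulation is the
#' included angle between a reference vector and a segment vector, given as
#' joint pairs with a `{side}` placeholder.
#'
#' @return A tibble with one row per articulation.
#' @export
articulations <- function() {
  tibble(
    articulation = names(.ARTICULATIONS),
    ref_origin = vapply(.ARTICULATIONS, function(a) a$ref[1], character(1)),
    ref_tip = vapply(.ARTICULATIONS, function(a) a$ref[2], character(1)),
    seg_origin = vapply(.ARTICULATIONS, function(a) a$seg[1], character(1)),
    seg_tip = vapply(.ARTICULATIONS, function(a) a$seg[2], character(1)),
    description = vapply(.ARTICULATIONS, function(a) a$description,
                         character(1))
  )
}

.resolve_side <- function(labels, side) {
  gsub("{side}", side, labels, fixed = TRUE)
}

#' Per-frame joint-angle series
#'
#' Computes one clinical angle per frame from a skeleton sequence, either in
#' 3D or after projecting both vectors onto an anatomical plane.  Frames
#' where either vector is degenerate (norm below `eps`) are marked missing
#' (`NA`), never interpolated.
#'
#' @param seq A `skeleton_sequence` (raw or preprocessed).
#' @param articulation One of [articulations()]`$articulation`.
#' @param side `"right"` or `"left"`.
#' @param plane `"coronal"`, `"sagittal"`, `"axial"` or `"3D"`.
#' @param eps Degeneracy threshold, metres.
#' @return An `angle_series` tibble with columns `frame`, `t`, `joint`,
#'   `side`, `plane`, `theta_deg`.
#' @export
angle_series <- function(seq, articulation = "shoulder_abduction",
                         side = c("right", "left"), plane = "coronal",
                         eps = 1e-9) {
  side <- match.arg(side)
  plane <- match.arg(plane, c(names(.PLANES), "3D"))
  if (!articulation %in% names(.ARTICULATIONS)) {
    abort(paste0("unknown articulation: '", articulation, "'"))
  }
  art <- .ARTICULATIONS[[articulation]]
  ref <- .resolve_side(art$ref, side)
  seg <- .resolve_side(art$seg, side)
  frames <- sort(unique(seq$frame))
  tmap <- seq$t[match(frames, seq$frame)]
  v1 <- .joint_matrix(seq, ref[2], frames) - .joint_matrix(seq, ref[1], frames)
  v2 <- .joint_matrix(seq, seg[2], frames) - .joint_matrix(seq, seg[1], frames)
  if (plane != "3D") {
    keep <- match(.PLANES[[plane]]$keep, c("x", "y", "z"))
    v1 <- v1[, keep, drop = FALSE]
    v2 <- v2[, keep, drop = FALSE]
  }
  theta <- .angle_rows(v1, v2, eps = eps)
  tibble::new_tibble(
    list(
      frame = frames, t = tmap,
      joint = rep(articulation, length(frames)),
      side = rep(side, length(frames)),
      plane = rep(plane, length(frames)),
      theta_deg = theta
    ),
    nrow = length(frames),
    class = "angle_series"
  )
}

#' Summarise an end-effector trajectory
#'
#' Range of motion comes from the articulation's angle series (max minus min,
#' ignoring missing frames).  Path length is the summed distance between
#' consecutive end-effector positions (projected coordinates when a plane is
#' given, 3D otherwise).  Covered area is the convex-hull area of the
#' end-effector path projected onto the requested plane; in 3D mode the
#' coronal projection is used for the hull.  Fewer than 3 distinct points or
#' a collinear path give area 0 with a warning.
#'
#' @param seq A `skeleton_sequence`.
#' @param end_effector Joint label whose path is summarised
#'   (e.g. `"right_wrist"`).
#' @param plane `"coronal"`, `"sagittal"`, `"axial"` or `"3D"`.
#' @param articulation Articulation used for the range of motion.
#' @param side `"right"` or `"left"`; defaults to the side encoded in
#'   `end_effector`.
#' @return A one-row tibble with `rom_deg`, `area_m2`, `path_length_m`,
#'   `n_frames`, plus a `policy` attribute echoing the settings.
#' @export
trajectory_summary <- function(seq, end_effector, plane = "coronal",
                               articulation = "shoulder_abduction",
                               side = NULL) {
  plane <- match.arg(plane, c(names(.PLANES), "3D"))
  if (is.null(side)) {
    side <- if (startsWith(end_effector, "left_")) "left" else "right"
  }
  frames <- sort(unique(seq$frame))
  pts <- .joint_matrix(seq, end_effector, frames)
  ang <- angle_series(seq, articulation = articulation, side = side,
                      plane = plane)
  th <- ang$theta_deg[!is.na(ang$theta_deg)]
  rom <- if (length(th) > 0L) max(th) - min(th) else 0
  if (plane != "3D") {
    keep <- match(.PLANES[[plane]]$keep, c("x", "y", "z"))
    path_pts <- pts[, keep, drop = FALSE]
    hull_pts <- path_pts
  } else {
    path_pts <- pts
    hull_pts <- pts[, 1:2, drop = FALSE]  # coronal projection for the hull
  }
  dp <- diff(path_pts)
  path_length <- sum(sqrt(rowSums(dp^2)))
  area <- .hull_area(hull_pts)
  out <- tibble(
    rom_deg = rom, area_m2 = area, path_length_m = path_length,
    n_frames = length(frames)
  )
  attr(out, "policy") <- list(
    end_effector = end_effector, plane = plane,
    articulation = articulation, side = side,
    area_method = "convex hull of projected end-effector path"
  )
  out
}

# Convex-hull area by the shoelace formula; degenerate paths -> 0 + warning.
.hull_area <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3L) {
    warn("degenerate path: fewer than 3 distinct points, area set to 0")
    return(0)
  }
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3L) {
    warn("degenerate path: collinear points, area set to 0")
    return(0)
  }
  px <- xy[h, 1]
  py <- xy[h, 2]
  area <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
  if (area < .Machine$double.eps) {
    warn("degenerate path: collinear points, area set to 0")
    return(0)
  }
  area
}
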