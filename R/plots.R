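# ggplot2 displays for the package's result types.

#' Bland-Altman plot
#'
#' Per-pair difference against per-pair mean, with the mean difference as a
#' solid line and the 95% limits of agreement as dashed lines.
#'
#' @param object A [bland_altman()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$pair_mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(object$lower, object$upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of the two methods (deg)",
      y = "Difference between methods (deg)",
      title = sprintf(
        "Bland-Altman agreement: bias %.2f, limits [%.2f, %.2f]",
        object$mean_diff, object$lower, object$upper
      )
    ) +
    ggplot2::theme_minimal()
}

#' Repeatability plot
#'
#' Between-session difference against the session mean, with the mean
#' difference (solid) and 95% repeatability limits (dashed).
#'
#' @param object A [repeatability()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.repeatability <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$pair_mean, y = .data$u)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_u, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(object$lower, object$upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of the two sessions (deg)",
      y = "Session 1 - session 2 (deg)",
      title = sprintf("Repeatability: CR %.2f deg, limits [%.2f, %.2f]",
                      object$cr, object$lower, object$upper)
    ) +
    ggplot2::theme_minimal()
}

#' Angle-series plot
#'
#' Joint-angle excursion over time.
#'
#' @param object An [angle_series()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.angle_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$theta_deg)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (s)", y = "Angle (deg)",
      title = sprintf("%s (%s, %s plane)", object$joint[1], object$side[1],
                      object$plane[1])
    ) +
    ggplot2::theme_minimal()
}

#' Plot cleaning stages for one joint coordinate
#'
#' Overlays the original and per-stage curves (raw, outliers removed,
#' interpolated, smoothed) of one joint's coordinate trace, mirroring the
#' original/smoothed curve displays of motion-analysis GUIs.
#'
#' @param pre A sequence from [preprocess_sequence()] with kept stages.
#' @param joint Joint label, e.g. `"right_wrist"`.
#' @param coord `"x"`, `"y"` or `"z"`.
#' @return A ggplot.
#' @export
plot_stages <- function(pre, joint, coord = c("y", "x", "z")) {
  coord <- match.arg(coord)
  stages <- attr(pre, "stages")
  if (is.null(stages)) {
    abort("sequence has no kept stages; rerun preprocess_sequence() with keep_stages = TRUE")
  }
  dat <- dplyr::bind_rows(lapply(names(stages), function(nm) {
    s <- stages[[nm]]
    rows <- s$joint == joint
    tibble(stage = nm, t = s$t[rows], value = s[[coord]][rows])
  }))
  dat$stage <- factor(dat$stage,
                      levels = c("raw", "deoutliered", "interpolated",
                                 "smoothed"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$value,
                                    colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = sprintf("%s.%s (m)", joint, coord),
                  colour = "Stage") +
    ggplot2::theme_minimal()
}
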