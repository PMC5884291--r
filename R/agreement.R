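# Method-comparison statistics: Bland-Altman limits of agreement between two
# measurement methods, and test-retest repeatability across two sessions with
# the coefficient of repeatability (CR).
#
# Conventions (fixed and echoed in every report):
#   * differences are first argument minus second (a - b, session1 - session2)
#   * sd of differences uses the sample (n - 1) denominator
#   * limits are centred on the mean difference: mean +/- 1.96 * sd
#   * CR = sqrt(sum(u^2) / n)  (root mean square, n denominator)
#   * points exactly on a limit count as within the limits

#' Bland-Altman agreement between two measurement methods
#'
#' For paired readings of the same quantity by two methods, computes the
#' per-pair difference `d = a - b` and mean `m = (a + b)/2`, the mean
#' difference (bias), the sample standard deviation of the differences, and
#' the 95% limits of agreement `mean(d) +/- 1.96 * sd(d)`.  Under an
#' approximately Gaussian difference distribution about 95% of differences
#' are expected to fall inside the limits; if that band is clinically
#' acceptable the two methods can be used interchangeably.
#'
#' @param data Data frame of paired measurements.
#' @param a,b Columns holding the two methods' readings (tidy-eval; default
#'   columns `a` and `b`).  Differences are `a - b`.
#' @return A `bland_altman` object: a list with elements `data` (tibble with
#'   `a`, `b`, `pair_mean`, `diff`, `within`), `n`, `mean_diff`, `sd_diff`,
#'   `lower`, `upper`, `n_outside`, `fraction_within`, `direction`.
#'   Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @examples
#' d <- tibble::tibble(a = c(10, 20, 30), b = c(11, 19, 31))
#' ba <- bland_altman(d)
#' glance(ba)
#' @export
bland_altman <- function(data, a = a, b = b) {
  va <- dplyr::pull(data, {{ a }})
  vb <- dplyr::pull(data, {{ b }})
  if (length(va) != length(vb)) abort("`a` and `b` must have equal length")
  keep <- is.finite(va) & is.finite(vb)
  if (!all(keep)) abort("non-finite measurements in `a` or `b`",
                        class = "kinagree_data_error")
  n <- length(va)
  if (n < 2L) abort("need at least 2 pairs", class = "kinagree_data_error")
  d <- va - vb
  m <- (va + vb) / 2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  lower <- mean_diff - 1.96 * sd_diff
  upper <- mean_diff + 1.96 * sd_diff
  within <- d >= lower & d <= upper
  dat <- tibble(a = va, b = vb, pair_mean = m, diff = d, within = within)
  if ("subject" %in% names(data)) dat$subject <- data$subject
  structure(
    list(
      data = dat, n = n, mean_diff = mean_diff, sd_diff = sd_diff,
      lower = lower, upper = upper,
      n_outside = sum(!within),
      fraction_within = mean(within),
      direction = "a - b"
    ),
    class = "bland_altman"
  )
}

#' Test-retest repeatability and coefficient of repeatability
#'
#' For one method measured twice on each subject, computes the per-subject
#' session difference `u = session1 - session2`, its mean and sample standard
#' deviation, the 95% repeatability limits `mean(u) +/- 1.96 * sd(u)`, and
#' the coefficient of repeatability `CR = sqrt(sum(u^2)/n)` — the bound below
#' which about 95% of repeat differences are expected when the mean
#' difference is near zero (British Standards convention).  `cr_percent`
#' expresses CR as a percentage of a stated reference angle (the protocol's
#' nominal 90 degrees by default).
#'
#' @param data Data frame with one row per subject.
#' @param session1,session2 Columns holding the two sessions' readings
#'   (tidy-eval; default columns `session1`, `session2`).
#' @param reference Positive reference angle in degrees for `cr_percent`.
#' @return A `repeatability` object: list with `data` (tibble with
#'   `session1`, `session2`, `pair_mean`, `u`, `within`), `n`, `mean_u`,
#'   `sd_u`, `lower`, `upper`, `cr`, `cr_percent`, `reference`, `direction`.
#' @examples
#' d <- tibble::tibble(session1 = c(91, 89, 92, 88),
#'                     session2 = c(90, 90, 90, 90))
#' repeatability(d)$cr
#' @export
repeatability <- function(data, session1 = session1, session2 = session2,
                          reference = 90) {
  s1 <- dplyr::pull(data, {{ session1 }})
  s2 <- dplyr::pull(data, {{ session2 }})
  if (length(s1) != length(s2)) {
    abort("sessions must have equal length", class = "kinagree_data_error")
  }
  if (!all(is.finite(s1)) || !all(is.finite(s2))) {
    abort("non-finite session measurements", class = "kinagree_data_error")
  }
  n <- length(s1)
  if (n < 2L) abort("need at least 2 subjects", class = "kinagree_data_error")
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0) {
    abort("`reference` must be a single positive angle in degrees")
  }
  u <- s1 - s2
  mean_u <- mean(u)
  sd_u <- stats::sd(u)
  lower <- mean_u - 1.96 * sd_u
  upper <- mean_u + 1.96 * sd_u
  within <- u >= lower & u <= upper
  cr <- sqrt(sum(u^2) / n)
  dat <- tibble(session1 = s1, session2 = s2,
                pair_mean = (s1 + s2) / 2, u = u, within = within)
  if ("subject" %in% names(data)) dat$subject <- data$subject
  structure(
    list(
      data = dat, n = n, mean_u = mean_u, sd_u = sd_u,
      lower = lower, upper = upper,
      cr = cr, cr_percent = 100 * cr / reference, reference = reference,
      n_outside = sum(!within), fraction_within = mean(within),
      direction = "session1 - session2"
    ),
    class = "repeatability"
  )
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat("Bland-Altman agreement (", x$direction, "), n = ", x$n, "\n",
      sep = "")
  cat(sprintf("  mean difference: %.*f\n", digits, x$mean_diff))
  cat(sprintf("  sd of differences: %.*f\n", digits, x$sd_diff))
  cat(sprintf("  95%% limits of agreement: [%.*f, %.*f]\n",
              digits, x$lower, digits, x$upper))
  cat(sprintf("  within limits: %d/%d (%.1f%%)\n",
              x$n - x$n_outside, x$n, 100 * x$fraction_within))
  invisible(x)
}

#' @export
print.repeatability <- function(x, digits = 4, ...) {
  cat("Repeatability (", x$direction, "), n = ", x$n, "\n", sep = "")
  cat(sprintf("  mean session difference: %.*f\n", digits, x$mean_u))
  cat(sprintf("  sd of session differences: %.*f\n", digits, x$sd_u))
  cat(sprintf("  95%% repeatability limits: [%.*f, %.*f]\n",
              digits, x$lower, digits, x$upper))
  cat(sprintf("  coefficient of repeatability: %.*f (%.2f%% of %g deg)\n",
              digits, x$cr, x$cr_percent, x$reference))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` or `repeatability` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(
    term = c("mean_diff", "sd_diff", "lower", "upper", "fraction_within"),
    estimate = c(x$mean_diff, x$sd_diff, x$lower, x$upper,
                 x$fraction_within)
  )
}

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(
    n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
    lower = x$lower, upper = x$upper,
    n_outside = x$n_outside, fraction_within = x$fraction_within
  )
}

#' @rdname repeatability
#' @param x A `repeatability` object.
#' @param ... Unused.
#' @export
tidy.repeatability <- function(x, ...) {
  tibble(
    term = c("mean_u", "sd_u", "lower", "upper", "cr", "cr_percent"),
    estimate = c(x$mean_u, x$sd_u, x$lower, x$upper, x$cr, x$cr_percent)
  )
}

#' @rdname repeatability
#' @export
glance.repeatability <- function(x, ...) {
  tibble(
    n = x$n, mean_u = x$mean_u, sd_u = x$sd_u,
    lower = x$lower, upper = x$upper,
    cr = x$cr, cr_percent = x$cr_percent, reference = x$reference
  )
}

#' Serialisable agreement / repeatability report
#'
#' Turns a fitted agreement or repeatability object into a plain named list
#' ready for [write_report_json()]: all scalar results, a policy block
#' echoing the fixed statistical conventions, and the scatter arrays needed
#' to redraw the Bland-Altman plot (solid mean line, dashed limit lines).
#' Empty optional fields are omitted, never null-padded.
#'
#' @param result A `bland_altman` or `repeatability` object.
#' @return A named list.
#' @export
agreement_report <- function(result) {
  policy <- list(
    difference_direction = result$direction,
    sd_denominator = "n-1",
    limits = "mean difference +/- 1.96 sd",
    boundary = "points on a limit count as within"
  )
  if (inherits(result, "bland_altman")) {
    list(
      type = "agreement",
      n = result$n,
      mean_diff = result$mean_diff,
      sd_diff = result$sd_diff,
      lower = result$lower,
      upper = result$upper,
      n_outside = result$n_outside,
      fraction_within = result$fraction_within,
      policy = policy,
      plot = list(pair_mean = result$data$pair_mean,
                  diff = result$data$diff)
    )
  } else if (inherits(result, "repeatability")) {
    list(
      type = "repeatability",
      n = result$n,
      mean_u = result$mean_u,
      sd_u = result$sd_u,
      lower = result$lower,
      upper = result$upper,
      cr = result$cr,
      cr_percent = result$cr_percent,
      reference = result$reference,
      n_outside = result$n_outside,
      fraction_within = result$fraction_within,
      policy = policy,
      plot = list(pair_mean = result$data$pair_mean,
                  diff = result$data$u)
    )
  } else {
    abort("`result` must be a bland_altman or repeatability object")
  }
}
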