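# Three-stage trajectory cleaning: outlier replacement -> block linear
# interpolation -> centred moving average, applied independently to each
# joint's x, y and z traces.  Every stage preserves series length.

.OUTLIER_POLICIES <- c("neighbors", "literal3", "global")

.sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Replace local trajectory outliers
#'
#' Scans the interior samples of a series and flags sample `i` when it falls
#' outside `mean - 1.96*sigma` .. `mean + 1.96*sigma`; a flagged sample is
#' replaced by the mean of its two neighbours.  The first and last samples
#' have no complete neighbourhood and are never replaced.  Thresholds and
#' replacements are computed from the original input in a single pass, so the
#' result is independent of scan order.
#'
#' Three choices of the window behind `mean`/`sigma` are selectable:
#'
#' * `"neighbors"` (default): mean and population sigma over the two
#'   neighbours `x[i-1], x[i+1]` only.  This is the only local variant that
#'   can actually flag a spike (see Details) and is consistent with replacing
#'   the flagged value by the neighbours' mean.
#' * `"literal3"`: mean and population sigma over the full 3-point window
#'   `x[i-1], x[i], x[i+1]` including the candidate.  For any 3 numbers the
#'   largest attainable `|x_i - mean|/sigma` is `2/sqrt(3)` (about 1.155), so
#'   this rule can never exceed the 1.96 threshold and flags nothing; it is
#'   retained for transparency.
#' * `"global"`: mean and population sigma of the whole series.
#'
#' @param x Numeric series (one coordinate trace), length >= 3.
#' @param policy Sigma-window policy, see above.
#' @return A list with `values` (cleaned series, same length), `windows`
#'   (tibble of flagged samples: `index`, `mean`, `sigma`, `lower`, `upper`,
#'   `flagged`), `n_flagged`, and `policy`.
#' @examples
#' remove_outliers(c(0, 0, 10, 0, 0))$values
#' remove_outliers(c(0, 0, 10, 0, 0), policy = "literal3")$n_flagged
#' @export
remove_outliers <- function(x, policy = c("neighbors", "literal3", "global")) {
  policy <- match.arg(policy)
  if (!is.numeric(x)) abort("`x` must be numeric")
  n <- length(x)
  if (n < 3L) {
    abort("too short: outlier removal needs at least 3 samples",
          class = "kinagree_data_error")
  }
  i <- 2:(n - 1L)
  left <- x[i - 1L]
  centre <- x[i]
  right <- x[i + 1L]
  if (policy == "neighbors") {
    m <- (left + right) / 2
    s <- abs(right - left) / 2
  } else if (policy == "literal3") {
    m <- (left + centre + right) / 3
    s <- sqrt(((left - m)^2 + (centre - m)^2 + (right - m)^2) / 3)
  } else {
    m <- rep(mean(x), n - 2L)
    s <- rep(.sd_pop(x), n - 2L)
  }
  lower <- m - 1.96 * s
  upper <- m + 1.96 * s
  flag <- centre < lower | centre > upper
  out <- x
  out[i[flag]] <- ((left + right) / 2)[flag]
  windows <- tibble::new_tibble(
    list(
      index = i[flag], mean = m[flag], sigma = s[flag],
      lower = lower[flag], upper = upper[flag],
      flagged = rep(TRUE, sum(flag))
    ),
    nrow = sum(flag)
  )
  list(values = out, windows = windows, n_flagged = sum(flag),
       policy = policy)
}

#' Block-wise linear interpolation
#'
#' Partitions the series into consecutive non-overlapping blocks of 10
#' samples.  Within each full block the 8 interior values are replaced by the
#' straight line joining the block's first and last values evaluated at their
#' positions; a trailing partial block (< 10 samples) is passed through
#' unchanged.  Applying the operation twice equals applying it once.
#'
#' @param x Numeric series.
#' @param block Block length (default 10).
#' @return Numeric series of the same length.
#' @examples
#' interpolate_blocks(c(0, 5, -5, 2, 8, 1, 7, -3, 4, 9))
#' @export
interpolate_blocks <- function(x, block = 10L) {
  if (!is.numeric(x)) abort("`x` must be numeric")
  block <- as.integer(block)
  if (block < 3L) abort("`block` must be at least 3")
  n <- length(x)
  nb <- n %/% block
  if (nb == 0L) return(x)
  out <- x
  starts <- seq.int(1L, by = block, length.out = nb)
  first <- x[starts]
  last <- x[starts + block - 1L]
  off <- seq_len(block - 2L)
  idx <- rep(starts, each = block - 2L) + rep(off, times = nb)
  slope <- (last - first) / (block - 1)
  out[idx] <- rep(first, each = block - 2L) +
    rep(off, times = nb) * rep(slope, each = block - 2L)
  out
}

#' Centred moving-average filter
#'
#' Each output sample is the mean of the centred window of up to `window_n`
#' input samples; at the series edges the window is clipped to the available
#' samples.  Output length equals input length, a constant series is left
#' unchanged, and every output value lies within the input range.
#'
#' @param x Numeric series.
#' @param window_n Window length; positive odd integer (default 5).
#' @return Numeric series of the same length.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), 3)
#' @export
moving_average <- function(x, window_n = 5L) {
  if (!is.numeric(x)) abort("`x` must be numeric")
  if (length(window_n) != 1L || !is.finite(window_n) || window_n < 1 ||
      window_n != as.integer(window_n) || as.integer(window_n) %% 2L == 0L) {
    abort("`window_n` must be a positive odd integer")
  }
  window_n <- as.integer(window_n)
  n <- length(x)
  if (n == 0L || window_n == 1L) return(x)
  if (max(x) == min(x)) return(x)
  h <- (window_n - 1L) %/% 2L
  idx <- seq_len(n)
  lo <- pmax(idx - h, 1L)
  hi <- pmin(idx + h, n)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Clean a skeleton sequence
#'
#' Runs the three cleaning stages in fixed order — outlier replacement,
#' block interpolation, moving-average smoothing — on every joint's x, y and
#' z traces independently.  Frame indices and timestamps are untouched.
#'
#' Stage-by-stage intermediates are kept (when `keep_stages = TRUE`) in the
#' `stages` attribute as a named list of skeleton tibbles (`raw`,
#' `deoutliered`, `interpolated`, `smoothed`) so the original and processed
#' curves can be plotted side by side; per-joint flag counts are in the
#' `outlier_counts` attribute.
#'
#' @param seq A `skeleton_sequence` (or conforming data frame).
#' @param policy Outlier sigma-window policy, see [remove_outliers()].
#' @param window_n Moving-average window, see [moving_average()].
#' @param block Interpolation block length, see [interpolate_blocks()].
#' @param keep_stages Keep per-stage intermediate tibbles?
#' @return A cleaned `skeleton_sequence` with attributes `stages`,
#'   `outlier_counts`, `policy` and `window_n`.
#' @export
preprocess_sequence <- function(seq,
                                policy = c("neighbors", "literal3", "global"),
                                window_n = 5L, block = 10L,
                                keep_stages = TRUE) {
  policy <- match.arg(policy)
  if (is.null(seq) || nrow(seq) == 0L) {
    abort("empty sequence", class = "kinagree_data_error")
  }
  groups <- split(seq_len(nrow(seq)), seq$joint)
  x1 <- seq$x; y1 <- seq$y; z1 <- seq$z       # after outlier removal
  counts <- integer(length(groups))
  names(counts) <- names(groups)
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    rows <- rows[order(seq$frame[rows])]
    groups[[g]] <- rows
    for (cc in c("x", "y", "z")) {
      res <- remove_outliers(seq[[cc]][rows], policy = policy)
      counts[g] <- counts[g] + res$n_flagged
      if (cc == "x") x1[rows] <- res$values
      else if (cc == "y") y1[rows] <- res$values
      else z1[rows] <- res$values
    }
  }
  x2 <- x1; y2 <- y1; z2 <- z1               # after interpolation
  x3 <- x1; y3 <- y1; z3 <- z1               # after smoothing
  for (rows in groups) {
    x2[rows] <- interpolate_blocks(x1[rows], block = block)
    y2[rows] <- interpolate_blocks(y1[rows], block = block)
    z2[rows] <- interpolate_blocks(z1[rows], block = block)
    x3[rows] <- moving_average(x2[rows], window_n = window_n)
    y3[rows] <- moving_average(y2[rows], window_n = window_n)
    z3[rows] <- moving_average(z2[rows], window_n = window_n)
  }
  base <- list(frame = seq$frame, t = seq$t, joint = seq$joint)
  rate <- attr(seq, "nominal_rate") %||% 30
  out <- new_skeleton_sequence(
    c(base, list(x = x3, y = y3, z = z3)),
    nominal_rate = rate
  )
  if (keep_stages) {
    mk <- function(x, y, z) {
      new_skeleton_sequence(c(base, list(x = x, y = y, z = z)),
                            nominal_rate = rate)
    }
    attr(out, "stages") <- list(
      raw = mk(seq$x, seq$y, seq$z),
      deoutliered = mk(x1, y1, z1),
      interpolated = mk(x2, y2, z2),
      smoothed = out
    )
  }
  attr(out, "outlier_counts") <- tibble::new_tibble(
    list(joint = names(counts), n_flagged = unname(counts)),
    nrow = length(counts)
  )
  attr(out, "policy") <- policy
  attr(out, "window_n") <- as.integer(window_n)
  out
}
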