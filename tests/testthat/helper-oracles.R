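# Independent brute-force oracles.  These are deliberately naive loop
# implementations, kept free of any shared code with the package internals,
# used to cross-check every cleaning stage and the angle computation.

oracle_remove_outliers <- function(x, policy = "neighbors") {
  n <- length(x)
  out <- x
  for (i in 2:(n - 1)) {
    left <- x[i - 1]; centre <- x[i]; right <- x[i + 1]
    if (policy == "neighbors") {
      w <- c(left, right)
      m <- (left + right) / 2
      s <- sqrt(sum((w - m)^2) / 2)
    } else if (policy == "literal3") {
      w <- c(left, centre, right)
      m <- sum(w) / 3
      s <- sqrt(sum((w - m)^2) / 3)
    } else {
      m <- sum(x) / n
      s <- sqrt(sum((x - m)^2) / n)
    }
    if (centre < m - 1.96 * s || centre > m + 1.96 * s) {
      out[i] <- (left + right) / 2
    }
  }
  out
}

oracle_interpolate_blocks <- function(x, block = 10) {
  n <- length(x)
  out <- x
  b <- 1
  while (b + block - 1 <= n) {
    first <- x[b]
    last <- x[b + block - 1]
    for (k in 1:(block - 2)) {
      out[b + k] <- first + k * (last - first) / (block - 1)
    }
    b <- b + block
  }
  out
}

oracle_moving_average <- function(x, window_n = 5) {
  n <- length(x)
  h <- (window_n - 1) / 2
  out <- numeric(n)
  for (i in 1:n) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    s <- 0
    for (j in lo:hi) s <- s + x[j]
    out[i] <- s / (hi - lo + 1)
  }
  out
}

# Angle via the cross-product / atan2 construction (independent of acos).
oracle_angle_deg <- function(p1, p2) {
  if (length(p1) == 2) {
    p1 <- c(p1, 0)
    p2 <- c(p2, 0)
  }
  cr <- c(
    p1[2] * p2[3] - p1[3] * p2[2],
    p1[3] * p2[1] - p1[1] * p2[3],
    p1[1] * p2[2] - p1[2] * p2[1]
  )
  atan2(sqrt(sum(cr^2)), sum(p1 * p2)) * 180 / pi
}
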