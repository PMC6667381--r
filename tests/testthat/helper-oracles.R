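# Independent oracles for the property tests. These re-derive results with
# different machinery (plain loops, lm(), numerical integration) so the
# implementation under test never checks itself.

# Exhaustive minimum-SSE search over contiguous 3-way partitions, written
# independently of segment_phases(): plain loops + lm(). Returns the sizes
# of the best partition and its SSE. Ties broken toward widest phase 2,
# mirroring the documented rule.
oracle_segmentation <- function(x, y, min_per_phase = 2L) {
  n <- length(x)
  best <- NULL
  for (n1 in min_per_phase:(n - 2L * min_per_phase)) {
    for (n2 in min_per_phase:(n - n1 - min_per_phase)) {
      n3 <- n - n1 - n2
      i1 <- 1:n1; i2 <- (n1 + 1):(n1 + n2); i3 <- (n1 + n2 + 1):n
      s1 <- sum(x[i1] * y[i1]) / sum(x[i1]^2)
      s3 <- sum(x[i3] * y[i3]) / sum(x[i3]^2)
      f2 <- stats::lm(y[i2] ~ x[i2])
      b2 <- unname(stats::coef(f2)[2])
      if (s1 <= b2) next
      sse <- sum((y[i1] - s1 * x[i1])^2) + sum(stats::resid(f2)^2) +
        sum((y[i3] - s3 * x[i3])^2)
      span <- x[max(i2)] - x[min(i2)]
      if (is.null(best) || sse < best$sse * (1 - 1e-9) - 1e-12 ||
          (abs(sse - best$sse) <= best$sse * 1e-9 + 1e-12 && span > best$span)) {
        best <- list(sizes = c(n1, n2, n3), sse = sse, span = span)
      }
    }
  }
  best
}

# Fixed-step RK4 integration of dc/dt = g - k c from c(0) = 0, returning
# c(T). Independent numerical check of the closed-form decay correction.
oracle_rk4_end_conc <- function(g, k, T, steps = 20000L) {
  h <- T / steps
  c <- 0
  f <- function(c) g - k * c
  for (i in seq_len(steps)) {
    k1 <- f(c)
    k2 <- f(c + h / 2 * k1)
    k3 <- f(c + h / 2 * k2)
    k4 <- f(c + h * k3)
    c <- c + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  c
}

# Noise-free generative response at density x (duplicate of the generator's
# formula, kept here so generator regressions are caught).
oracle_response <- function(x, A_s, d_s, A_d, d_d) {
  A_s * pmin(x / d_s, 1) + A_d * pmin(x / d_d, 1)
}
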