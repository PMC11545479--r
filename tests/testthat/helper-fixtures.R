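# shared fixtures, built in code at test time

# a single plane-wave height map: z = a * cos(2*pi*x/period + phase)
sinusoid_map <- function(size = 128, pixel_size = 10, period = 100, a = 1,
                         angle = 0, phase = 0) {
  xv <- (seq_len(size) - 1) * pixel_size
  fx <- cos(angle) / period
  fy <- sin(angle) / period
  z <- a * cos(outer(2 * pi * fx * xv, 2 * pi * fy * xv, "+") + phase)
  heightmap(z, pixel_size = pixel_size, name = "sinusoid")
}

# brute-force max Feret: all pixel pairs, no hull shortcut (independent oracle)
feret_brute <- function(mask, pixel_size) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 2) return(0)
  max(stats::dist(pts)) * pixel_size / 1000
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (independent oracle for small tie-free samples)
mw_exact_enum <- function(x, y) {
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]) - n * (n + 1) / 2)
  # two-sided: distance from the null mean
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
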