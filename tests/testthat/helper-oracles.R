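# Independent oracles used to cross-check the measurement chain. These are
# deliberately coded against different primitives than the package:
# pracma::polyarea for polygon areas, grDevices::chull for convex hulls,
# and plain sum formulas for the radial statistics.

# sigma(R)/Rbar of a harmonic radial profile, evaluated by dense sampling
# of r(theta) directly (never touches the package's contour path).
acirc_oracle <- function(R0, harmonics, n = 20000L) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- rep(R0, n)
  for (i in seq_len(NROW(harmonics))) {
    r <- r + R0 * harmonics$a[i] * cos(harmonics$k[i] * theta +
                                         harmonics$phi[i])
  }
  mu <- sum(r) / n
  sqrt(sum((r - mu)^2) / n) / mu
}

# sigma(R)/Rbar of an arbitrary point cloud about the mean point (sum
# formulas, population divisor).
acirc_points_oracle <- function(pts) {
  cx <- sum(pts[, 1]) / nrow(pts)
  cy <- sum(pts[, 2]) / nrow(pts)
  r <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
  sqrt(sum((r - mean(r))^2) / length(r)) / mean(r)
}

# Polygon area of ordered vertices via pracma.
polyarea_oracle <- function(pts) {
  abs(pracma::polyarea(pts[, 1], pts[, 2]))
}

# Convex-hull area of an unordered point cloud.
hull_area_oracle <- function(pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])
  polyarea_oracle(pts[h, , drop = FALSE])
}

# Minimum distance from point p to the closed polyline through vertices v
# (point-to-segment distances over every edge).
point_to_polyline_dist <- function(p, v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  abx <- b[, 1] - a[, 1]
  aby <- b[, 2] - a[, 2]
  apx <- p[1] - a[, 1]
  apy <- p[2] - a[, 2]
  len2 <- abx^2 + aby^2
  t <- pmin(pmax(ifelse(len2 > 0, (apx * abx + apy * aby) / len2, 0), 0), 1)
  min(sqrt((apx - t * abx)^2 + (apy - t * aby)^2))
}

# Random harmonic shape (star-shaped by construction); draws from the
# caller's RNG stream.
random_shape <- function(R0_range = c(20, 45), amp_range = c(0.02, 0.12),
                         centre = NULL, n_samples = 512L) {
  R0 <- runif(1, R0_range[1], R0_range[2])
  m <- sample(2:3, 1)
  h <- data.frame(k = sample(2:6, m),
                  a = runif(m, amp_range[1], amp_range[2]),
                  phi = runif(m, 0, 2 * pi))
  rmax <- R0 * (1 + sum(h$a))
  if (is.null(centre)) centre <- c(rmax + 10, rmax + 10)
  synthetic_shape(R0, h, centre = centre, n_samples = n_samples)
}

# Real-valued boundary samples of a random shape, as a plain matrix.
random_contour_points <- function(...) {
  shape_to_points(random_shape(...), round_px = FALSE)$points
}
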