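# Independent oracles used across the suite. These deliberately avoid the
# package's own tangent/inflection machinery.

# Dense numerical-differentiation Cobb oracle: evaluates a coordinate
# function at `n` points, takes central-difference first and second
# derivatives, locates inflections as sign changes of the second derivative
# (with a relative zero band), and measures each segment's angle between the
# boundary tangents (where the tilt is extremal for monotone-convexity
# segments).
cobb_oracle_dense <- function(f, lo, hi, n = 1e4, min_segment = 20) {
  yy <- seq(lo, hi, length.out = n)
  h <- yy[2] - yy[1]
  v <- f(yy)
  d1 <- numeric(n)
  d1[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  d1[1] <- (v[2] - v[1]) / h
  d1[n] <- (v[n] - v[n - 1]) / h
  d2 <- (v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]) / h^2
  ym <- yy[2:(n - 1)]
  scale <- max(abs(d2))
  interior <- numeric(0)
  if (scale > 1e-8) {
    s <- integer(length(d2))
    s[d2 > 1e-4 * scale] <- 1L
    s[d2 < -1e-4 * scale] <- -1L
    nz <- which(s != 0L)
    if (length(nz) > 1L) {
      flip <- which(s[nz[-1]] != s[nz[-length(nz)]])
      for (k in flip) {
        i <- nz[k]; j <- nz[k + 1L]
        w <- abs(d2[i]) / (abs(d2[i]) + abs(d2[j]))
        interior <- c(interior, (1 - w) * ym[i] + w * ym[j])
      }
    }
  }
  interior <- interior[interior > lo + min_segment & interior < hi - min_segment]
  while (length(interior) > 1L && any(diff(interior) < min_segment)) {
    k <- which(diff(interior) < min_segment)[1]
    interior <- interior[-c(k, k + 1L)]
  }
  anchors <- c(lo, interior, hi)
  sl <- approx(yy, d1, xout = anchors)$y
  ang <- abs(diff(atan(sl))) * 180 / pi
  list(anchors = anchors, angles = ang, primary = max(ang))
}

# Brute-force two-pass Pearson correlation per Eq.-style definition:
# standardize each sequence by its own mean and (N-1)-normalized SD, then
# average the products over N-1.
pcc_brute_force <- function(a, b) {
  za <- (a - mean(a)) / sd(a)
  zb <- (b - mean(b)) / sd(b)
  sum(za * zb) / (length(a) - 1)
}

# random proper rotation (QR-based, independent of rotation_axis_angle)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# spine_curve through exact samples of a planar sine in the frontal plane
sine_curve <- function(A, L, n_pts = 80, n_samples = 100) {
  ys <- seq(0, L, length.out = n_pts)
  smooth_curve(cbind(A * sin(2 * pi * ys / L), ys, rep(0, n_pts)),
               "auto", n_samples)
}

# non-coplanar 4-marker set with realistic trunk-scale lever arms
marker_quad <- function() {
  rbind(C7 = c(2, 450, 32), L5 = c(-1, 0, 36),
        PSIS_L = c(-45, -60, 25), PSIS_R = c(45, -60, 25))
}
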