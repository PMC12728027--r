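# Orthogonal-projection triangulation between the two radiograph views.
#
# Biplanar geometry: the frontal view observes (x, y), the lateral view
# (z, y). Projections are modelled as orthogonal, so a 3D point is recovered
# by taking x from the frontal observation, z from the lateral one, and
# reconciling the two y observations.

#' Orthogonally project a 3D point into both view planes
#'
#' Exact inverse of [triangulate_marker()]: the frontal projection keeps
#' (x, y), the lateral projection keeps (z, y).
#'
#' @param p a 3D point `c(x, y, z)` or an n x 3 matrix (mm, shared frame).
#' @return list with components `frontal` and `lateral`, each an `(u, y)` mm
#'   point (or n x 2 matrix).
#' @export
project_to_views <- function(p) {
  vec_in <- is.null(dim(p))
  p <- as_pts3(p)
  if (any(!is.finite(p))) stop("point coordinates must be finite", call. = FALSE)
  f <- cbind(u = p[, 1], y = p[, 2])
  l <- cbind(u = p[, 3], y = p[, 2])
  if (vec_in && nrow(p) == 1L) list(frontal = f[1L, ], lateral = l[1L, ])
  else list(frontal = f, lateral = l)
}

#' Triangulate one marker from its two view observations
#'
#' x is taken from the frontal observation, z from the lateral one, and y is
#' the arithmetic mean of the two observed heights. The height discrepancy
#' `|y_frontal - y_lateral|` is returned as a per-marker quality metric and
#' flagged (with a warning) when it exceeds `warn_threshold_mm`; it is never
#' a hard failure.
#'
#' @param p_frontal `(x, y)` mm observation in the frontal view.
#' @param p_lateral `(z, y)` mm observation in the lateral view.
#' @param warn_threshold_mm flag threshold for the y discrepancy (default 15).
#' @param name optional marker name used in the warning.
#' @return list with `point` (`c(x, y, z)` mm), `y_residual` (mm) and
#'   `flagged` (logical).
#' @export
triangulate_marker <- function(p_frontal, p_lateral, warn_threshold_mm = 15,
                               name = NULL) {
  p_frontal <- as.numeric(p_frontal); p_lateral <- as.numeric(p_lateral)
  stopifnot(length(p_frontal) == 2L, length(p_lateral) == 2L)
  y <- (p_frontal[2] + p_lateral[2]) / 2
  res <- abs(p_frontal[2] - p_lateral[2])
  flagged <- res > warn_threshold_mm
  if (flagged)
    warning(sprintf("marker%s y-residual %.1f mm exceeds %.1f mm",
                    if (is.null(name)) "" else paste0(" ", name),
                    res, warn_threshold_mm), call. = FALSE)
  list(point = c(x = p_frontal[1], y = y, z = p_lateral[1]),
       y_residual = res, flagged = flagged)
}

#' Triangulate a named marker set from two annotated views
#'
#' Converts the marker picks of both annotations to millimetres, matches
#' markers by name, and triangulates each pair.
#'
#' @param ann_frontal,ann_lateral [annotation2d()] objects for the two views.
#' @param frame_frontal,frame_lateral the corresponding [radiograph_frame()]s.
#' @param warn_threshold_mm see [triangulate_marker()].
#' @return list with `points` (n x 3 named matrix, mm), `y_residuals`
#'   (named vector, mm) and `flagged` (named logical).
#' @export
triangulate_markers <- function(ann_frontal, frame_frontal,
                                ann_lateral, frame_lateral,
                                warn_threshold_mm = 15) {
  mf <- pixel_to_mm(ann_frontal$markers, frame_frontal)
  ml <- pixel_to_mm(ann_lateral$markers, frame_lateral)
  rownames(mf) <- rownames(ann_frontal$markers)
  rownames(ml) <- rownames(ann_lateral$markers)
  common <- intersect(rownames(mf), rownames(ml))
  if (length(common) < 1L)
    stop("no marker names common to both views", call. = FALSE)
  pts <- matrix(NA_real_, length(common), 3L,
                dimnames = list(common, c("x", "y", "z")))
  res <- stats::setNames(numeric(length(common)), common)
  flg <- stats::setNames(logical(length(common)), common)
  for (nm in common) {
    tr <- triangulate_marker(mf[nm, ], ml[nm, ], warn_threshold_mm, name = nm)
    pts[nm, ] <- tr$point
    res[nm] <- tr$y_residual
    flg[nm] <- tr$flagged
  }
  list(points = pts, y_residuals = res, flagged = flg)
}

# Sort a 2-column (u, y) polyline by y and collapse duplicate y values by
# averaging u. Hand-drawn lines may backtrack locally; reject if more than
# `max_reordered` of the points had to move.
preprocess_polyline <- function(p, max_reordered = 0.05) {
  p <- as_pts2(p)
  if (nrow(p) < 2L) stop("polyline needs at least 2 points", call. = FALSE)
  ord <- order(p[, 2])
  frac <- mean(ord != seq_len(nrow(p)))
  rev_frac <- mean(rev(ord) != seq_len(nrow(p)))
  # accept either drawing direction; measure disorder against the closer one
  frac <- min(frac, rev_frac)
  if (frac > max_reordered)
    stop(sprintf(
      "polyline is not monotone in y (%.0f%% of points reordered)",
      100 * frac), call. = FALSE)
  p <- p[ord, , drop = FALSE]
  if (anyDuplicated(p[, 2])) {
    u <- tapply(p[, 1], factor(p[, 2], levels = unique(p[, 2])), mean)
    y <- unique(p[, 2])
    p <- cbind(as.numeric(u), y)
  }
  colnames(p) <- c("u", "y")
  p
}

#' Fuse the two 2D spinal-line drawings into a 3D polyline
#'
#' Both drawn lines are parameterized by the vertical coordinate y over the
#' intersection of their y-ranges; x(y) is linearly interpolated from the
#' frontal line and z(y) from the lateral line, sampled at `n_samples` evenly
#' spaced heights.
#'
#' @param line_frontal,line_lateral `(u, y)` mm polylines (>= 2 points each).
#'   Points are reordered by y; lines that backtrack in y by more than 5% of
#'   their points are rejected.
#' @param n_samples number of evenly spaced samples (default 100).
#' @return n x 3 matrix `(x, y, z)` mm with strictly increasing y spanning
#'   exactly the y-overlap of the two lines.
#' @export
triangulate_polyline <- function(line_frontal, line_lateral, n_samples = 100) {
  f <- preprocess_polyline(line_frontal)
  l <- preprocess_polyline(line_lateral)
  lo <- max(min(f[, 2]), min(l[, 2]))
  hi <- min(max(f[, 2]), max(l[, 2]))
  if (!(hi > lo))
    stop("the two line drawings have no overlapping y-range", call. = FALSE)
  yg <- seq(lo, hi, length.out = n_samples)
  x <- stats::approx(f[, 2], f[, 1], xout = yg, ties = mean)$y
  z <- stats::approx(l[, 2], l[, 1], xout = yg, ties = mean)$y
  cbind(x = x, y = yg, z = z)
}
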