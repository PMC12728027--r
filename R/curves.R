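# Smoothing-spline spinal curve model, rotation+translation-only Procrustes
# superimposition, and the per-plane Pearson shape correlation.

#' Smooth and regularly resample a 3D spinal line
#'
#' Fits independent penalized smoothing splines x(y) and z(y) to a 3D
#' polyline (the frontal and sagittal deviations as functions of the vertical
#' coordinate) and resamples both at `n_samples` regularly spaced heights.
#' With `smoothing = "auto"` the penalty is selected by generalized
#' cross-validation; a numeric value is passed through as the `spar`
#' smoothing parameter of [stats::smooth.spline()].
#'
#' @param pts n x 3 `(x, y, z)` polyline, mm; >= 4 points with weakly
#'   monotone y (points are reordered by y, duplicate heights averaged).
#' @param smoothing `"auto"` (GCV) or a numeric `spar` in (0, 1.5].
#' @param n_samples number of regular samples (default 100, minimum 10).
#' @param label optional source label, e.g. `"SPL"` or `"ISL"`.
#' @return An object of class `spine_curve`: the two spline fits, the regular
#'   y grid, and the sampled n x 3 point matrix (which evaluates the stored
#'   splines exactly).
#' @export
smooth_curve <- function(pts, smoothing = "auto", n_samples = 100,
                         label = NULL) {
  pts <- as_pts3(pts)
  ord <- order(pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  if (anyDuplicated(pts[, 2])) {
    fac <- factor(pts[, 2], levels = unique(pts[, 2]))
    pts <- cbind(as.numeric(tapply(pts[, 1], fac, mean)),
                 unique(pts[, 2]),
                 as.numeric(tapply(pts[, 3], fac, mean)))
  }
  if (nrow(pts) < 4L)
    stop("need at least 4 points with distinct heights to fit a spline",
         call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (n_samples < 10L) stop("n_samples must be at least 10", call. = FALSE)
  fit1 <- function(v) {
    if (identical(smoothing, "auto"))
      stats::smooth.spline(pts[, 2], v, cv = FALSE, keep.data = FALSE)
    else
      stats::smooth.spline(pts[, 2], v, spar = as.numeric(smoothing),
                           keep.data = FALSE)
  }
  fx <- fit1(pts[, 1])
  fz <- fit1(pts[, 3])
  yg <- seq(min(pts[, 2]), max(pts[, 2]), length.out = n_samples)
  sampled <- cbind(x = stats::predict(fx, yg)$y, y = yg,
                   z = stats::predict(fz, yg)$y)
  structure(
    list(label = label, fit_x = fx, fit_z = fz, y = yg, points = sampled,
         smoothing = smoothing),
    class = "spine_curve"
  )
}

# spline fit for the coordinate of a given anatomical plane
plane_fit <- function(curve, plane = c("frontal", "sagittal")) {
  plane <- match.arg(plane)
  if (plane == "frontal") curve$fit_x else curve$fit_z
}

#' Evaluate a spine curve (or its derivatives) at arbitrary heights
#'
#' @param curve a [smooth_curve()] result.
#' @param y heights (mm) at which to evaluate.
#' @param plane `"frontal"` (x coordinate) or `"sagittal"` (z coordinate).
#' @param deriv derivative order 0, 1 or 2 with respect to y.
#' @return numeric vector of coordinate values (or derivatives).
#' @export
eval_curve <- function(curve, y, plane = c("frontal", "sagittal"), deriv = 0) {
  stopifnot(inherits(curve, "spine_curve"))
  stats::predict(plane_fit(curve, plane), y, deriv = deriv)$y
}

#' @export
print.spine_curve <- function(x, ...) {
  cat(sprintf("<spine_curve>%s %d samples, y in [%.1f, %.1f] mm\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              length(x$y), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
plot.spine_curve <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$points[, 1], x$points[, 2], type = "l",
                 xlab = "x (mm, frontal deviation)", ylab = "y (mm, cranial)",
                 main = paste(x$label, "frontal"), ...)
  graphics::plot(x$points[, 3], x$points[, 2], type = "l",
                 xlab = "z (mm, posterior deviation)", ylab = "y (mm, cranial)",
                 main = paste(x$label, "sagittal"), ...)
  invisible(x)
}

#' Resample two curves onto their common height range
#'
#' The skin (SPL) and vertebral (ISL) lines span different landmark ranges;
#' both are re-evaluated on a common regular grid over the intersection of
#' their y-ranges so their shapes can be paired point-by-point.
#'
#' @param spl,isl [smooth_curve()] results.
#' @param n_samples grid size (default 100).
#' @return object of class `curve_pair`: `y` (common grid), `spl` and `isl`
#'   (n x 3 matrices), `n`.
#' @export
pair_curves <- function(spl, isl, n_samples = 100) {
  stopifnot(inherits(spl, "spine_curve"), inherits(isl, "spine_curve"))
  lo <- max(min(spl$y), min(isl$y))
  hi <- min(max(spl$y), max(isl$y))
  if (!(hi > lo))
    stop("curves have no overlapping y-range", call. = FALSE)
  yg <- seq(lo, hi, length.out = n_samples)
  at <- function(cv) cbind(x = eval_curve(cv, yg, "frontal"), y = yg,
                           z = eval_curve(cv, yg, "sagittal"))
  structure(list(y = yg, spl = at(spl), isl = at(isl), n = n_samples),
            class = "curve_pair")
}

#' Rotation + translation Procrustes superimposition (no scaling)
#'
#' Superimposes the moving point set onto the reference by the proper
#' rotation and translation minimizing the summed squared distances (Kabsch
#' closed form); the scale factor is fixed at 1 so the centroid size of the
#' moving set is preserved. Used to compare spinal line shapes irrespective
#' of global posture (vertical translation and global rotation).
#'
#' @param reference,moving n x 3 point matrices with equal n, or
#'   [smooth_curve()] objects resampled to the same number of points.
#'   Conventionally the ISL is the moving set, aligned onto the SPL.
#' @return list of class `procrustes_alignment`: `points` (aligned moving
#'   set), `rotation`, `translation`, `disparity` (summed squared residual).
#' @export
procrustes_align <- function(reference, moving) {
  pr <- if (inherits(reference, "spine_curve")) reference$points else as_pts3(reference)
  pm <- if (inherits(moving, "spine_curve")) moving$points else as_pts3(moving)
  if (nrow(pr) != nrow(pm))
    stop("reference and moving curves must be sampled to the same N",
         call. = FALSE)
  k <- kabsch(pm, pr)
  aligned <- sweep(pm %*% t(k$rotation), 2, k$translation, "+")
  colnames(aligned) <- c("x", "y", "z")
  structure(
    list(points = aligned, rotation = k$rotation, translation = k$translation,
         disparity = sum((aligned - pr)^2)),
    class = "procrustes_alignment"
  )
}

#' Per-plane Pearson correlation between paired spinal lines
#'
#' Pearson correlation between the SPL and ISL coordinate sequences of one
#' anatomical plane (frontal: x, sagittal: z), computed from the standardized
#' sequences, i.e. `sum(((SPL_i - mu_SPL)/sigma_SPL) *
#' ((ISL_i - mu_ISL)/sigma_ISL)) / (N - 1)` with each sequence centred by its
#' own mean and scaled by its own (N-1)-normalized standard deviation. The
#' implementation uses the algebraically identical ratio
#' `S_xy / sqrt(S_xx S_yy)` of centred sums so that identical and negated
#' sequences return exactly 1 and -1.
#'
#' @param pair a [pair_curves()] result (after Procrustes alignment of the
#'   ISL, see [procrustes_align()]), or any list with n x 3 matrices `spl`
#'   and `isl`.
#' @param plane `"frontal"` or `"sagittal"`.
#' @return correlation in `[-1, 1]`.
#' @details Errors if either sequence has zero variance (a flat curve has no
#'   defined shape correlation); the error names the offending curve.
#' @export
pcc_per_plane <- function(pair, plane = c("frontal", "sagittal")) {
  plane <- match.arg(plane)
  idx <- if (plane == "frontal") 1L else 3L
  a <- as_pts3(pair$spl)[, idx]
  b <- as_pts3(pair$isl)[, idx]
  if (length(a) != length(b))
    stop("SPL and ISL sequences must have equal length", call. = FALSE)
  da <- a - mean(a); db <- b - mean(b)
  saa <- sum(da^2); sbb <- sum(db^2)
  if (saa == 0)
    stop(sprintf("undefined correlation: SPL %s-plane sequence has zero variance",
                 plane), call. = FALSE)
  if (sbb == 0)
    stop(sprintf("undefined correlation: ISL %s-plane sequence has zero variance",
                 plane), call. = FALSE)
  sum(da * db) / sqrt(saa * sbb)
}

#' Centroid size of a point configuration
#'
#' Root-mean-square distance of the points to their centroid; the size
#' measure that a rotation+translation-only Procrustes superimposition must
#' leave unchanged.
#'
#' @param pts n x 3 point matrix.
#' @return centroid size (mm).
#' @export
centroid_size <- function(pts) {
  pts <- as_pts3(pts)
  sqrt(mean(rowSums(sweep(pts, 2, colMeans(pts))^2)))
}
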