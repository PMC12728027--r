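# Cobb angles from a smoothed spinal line: curve segments are delimited by
# the inflection points of the plane coordinate (plus the curve endpoints as
# boundary anchors), tangents are estimated by local linear regression at the
# segment boundaries, and the Cobb angle of a segment is the angle between
# its two boundary tangents.

#' Locate curvature inflection points of a spinal curve
#'
#' Evaluates the second derivative of the plane coordinate with respect to y
#' on a dense grid, finds sign changes, and refines each to a root by
#' bisection. Spurious wiggles are suppressed two ways: second derivatives
#' below 1e-6 of the curve's maximum curvature count as zero, and interior
#' inflections delimiting a segment shorter than `min_segment_mm` are dropped
#' pairwise (preserving convexity alternation). The curve endpoints are
#' always included as boundary anchors.
#'
#' @param curve a [smooth_curve()] result (>= 10 samples).
#' @param plane `"frontal"` or `"sagittal"`.
#' @param min_segment_mm minimum segment length (default 20 mm).
#' @return list with `interior` (refined interior inflection heights, possibly
#'   empty), `anchors` (`c(y_min, interior, y_max)`) and `plane`.
#' @export
find_inflections <- function(curve, plane = c("frontal", "sagittal"),
                             min_segment_mm = 20) {
  stopifnot(inherits(curve, "spine_curve"))
  plane <- match.arg(plane)
  if (length(curve$y) < 10L)
    stop("curve must have at least 10 samples", call. = FALSE)
  fit <- plane_fit(curve, plane)
  rng <- range(curve$y)
  grid <- seq(rng[1], rng[2], length.out = max(512L, 4L * length(curve$y)))
  d2 <- stats::predict(fit, grid, deriv = 2)$y
  scale <- max(abs(d2))
  interior <- numeric(0)
  if (scale > 1e-8) {
    tol <- 1e-6 * scale
    s <- integer(length(d2))
    s[d2 > tol] <- 1L
    s[d2 < -tol] <- -1L
    nz <- which(s != 0L)
    if (length(nz) > 1L) {
      flips <- which(s[nz[-1]] != s[nz[-length(nz)]])
      f2 <- function(v) stats::predict(fit, v, deriv = 2)$y
      for (k in flips) {
        a <- grid[nz[k]]; b <- grid[nz[k + 1L]]
        root <- tryCatch(stats::uniroot(f2, c(a, b))$root,
                         error = function(e) (a + b) / 2)
        interior <- c(interior, root)
      }
    }
  }
  interior <- sort(interior)
  # drop inflections hugging an endpoint, then spurious close pairs
  interior <- interior[interior > rng[1] + min_segment_mm &
                         interior < rng[2] - min_segment_mm]
  repeat {
    if (length(interior) < 2L) break
    gaps <- diff(interior)
    j <- which(gaps < min_segment_mm)
    if (!length(j)) break
    interior <- interior[-c(j[1], j[1] + 1L)]
  }
  list(interior = interior, anchors = c(rng[1], interior, rng[2]),
       plane = plane)
}

#' Curve tangent by local linear regression
#'
#' Ordinary least-squares slope `d(coord)/dy` of the smoothed curve around a
#' height of interest. The regression is fitted to 25 dense evaluations of
#' the stored spline within `|y - y0| <= window_mm / 2` (clipped at the curve
#' ends), so it always has far more than the minimum of 5 points a stable
#' fit needs. A window at least as long as the curve falls back to a global
#' fit with a warning.
#'
#' @param curve a [smooth_curve()] result.
#' @param plane `"frontal"` or `"sagittal"`.
#' @param y0 height (mm) at which the tangent is wanted; must lie within the
#'   curve's y-range.
#' @param window_mm regression window (default 12 mm, about half a vertebral
#'   height). Smaller windows track the tangent more faithfully on strongly
#'   curved spines but amplify residual spline ripple; the spline has already
#'   absorbed the measurement noise.
#' @return the tangent slope (dimensionless, mm/mm).
#' @export
local_tangent <- function(curve, plane = c("frontal", "sagittal"), y0,
                          window_mm = 12) {
  stopifnot(inherits(curve, "spine_curve"))
  plane <- match.arg(plane)
  rng <- range(curve$y)
  if (y0 < rng[1] - 1e-9 || y0 > rng[2] + 1e-9)
    stop(sprintf("y0 = %.1f outside the curve range [%.1f, %.1f]",
                 y0, rng[1], rng[2]), call. = FALSE)
  if (window_mm >= diff(rng)) {
    warning("regression window exceeds the curve; falling back to a global fit",
            call. = FALSE)
    lo <- rng[1]; hi <- rng[2]
  } else {
    lo <- max(rng[1], y0 - window_mm / 2)
    hi <- min(rng[2], y0 + window_mm / 2)
  }
  yy <- seq(lo, hi, length.out = 25L)
  vv <- stats::predict(plane_fit(curve, plane), yy)$y
  dy <- yy - mean(yy)
  sum(dy * (vv - mean(vv))) / sum(dy^2)
}

#' Cobb measurements for every curve segment in one plane
#'
#' Splits the curve at its interior inflection points (endpoints as boundary
#' anchors), estimates the boundary tangents by [local_tangent()], and
#' reports for each segment the unsigned angle between its two boundary
#' tangents, `|atan(s_upper) - atan(s_lower)|` in degrees, together with the
#' segment's convexity (sign of the second derivative at the segment
#' midpoint; in the sagittal plane, with z increasing posteriorly, negative
#' convexity means posteriorly convex).
#'
#' @inheritParams find_inflections
#' @param window_mm tangent regression window, see [local_tangent()].
#' @return data.frame with columns `lower_y`, `upper_y`, `slope_lower`,
#'   `slope_upper`, `angle_deg`, `convexity`; the interior inflection heights
#'   are attached as attribute `"interior"`.
#' @export
cobb_segments <- function(curve, plane = c("frontal", "sagittal"),
                          window_mm = 12, min_segment_mm = 20) {
  plane <- match.arg(plane)
  infl <- find_inflections(curve, plane, min_segment_mm)
  a <- infl$anchors
  slopes <- vapply(a, function(y0) local_tangent(curve, plane, y0, window_mm),
                   numeric(1))
  fit <- plane_fit(curve, plane)
  n_seg <- length(a) - 1L
  mids <- (a[-1] + a[-length(a)]) / 2
  conv <- sign(stats::predict(fit, mids, deriv = 2)$y)
  out <- data.frame(
    lower_y = a[-length(a)], upper_y = a[-1],
    slope_lower = slopes[-length(slopes)], slope_upper = slopes[-1],
    angle_deg = abs(atan(slopes[-1]) - atan(slopes[-length(slopes)])) * 180 / pi,
    convexity = conv
  )
  attr(out, "interior") <- infl$interior
  out
}

#' Frontal (scoliotic) Cobb angles
#'
#' Cobb angle of every frontal-plane curve segment of a smoothed spinal line,
#' and the primary curve (the segment with the largest angle) — the clinical
#' frontal Cobb angle. A straight line yields a single segment with angle ~0.
#'
#' @inheritParams cobb_segments
#' @return list of class `cobb_result` with `measurements` (the segment
#'   table from [cobb_segments()]), `primary` (row index of the largest
#'   angle) and `primary_angle` (degrees).
#' @export
cobb_frontal <- function(curve, window_mm = 12, min_segment_mm = 20) {
  segs <- cobb_segments(curve, "frontal", window_mm, min_segment_mm)
  i <- which.max(segs$angle_deg)
  structure(list(plane = "frontal", measurements = segs, primary = i,
                 primary_angle = segs$angle_deg[i]),
            class = "cobb_result")
}

#' Kyphotic and lordotic (sagittal) Cobb angles
#'
#' Expects a double sagittal curve: exactly one interior inflection
#' separating a posteriorly convex (kyphotic) from an anteriorly convex
#' (lordotic) segment. Convexity is read from the sign of z'' in each segment
#' (z increases posteriorly, so z'' < 0 means posteriorly convex); mirroring
#' the curve therefore swaps the two labels while leaving the angles
#' unchanged. With more than one interior inflection the two largest-angle
#' segments are used, with a warning. A monotone-convexity profile (no
#' interior inflection) raises a single-curve error.
#'
#' @inheritParams cobb_segments
#' @return list of class `cobb_sagittal` with components `kyphotic` and
#'   `lordotic`, each a one-row segment table (see [cobb_segments()]).
#' @export
cobb_sagittal <- function(curve, window_mm = 12, min_segment_mm = 20) {
  segs <- cobb_segments(curve, "sagittal", window_mm, min_segment_mm)
  if (nrow(segs) < 2L)
    stop(paste("single-curve sagittal profile: no interior inflection",
               "separates a kyphotic from a lordotic segment"), call. = FALSE)
  if (nrow(segs) > 2L) {
    warning(sprintf(
      "sagittal profile has %d interior inflections; using the two largest-angle segments",
      nrow(segs) - 1L), call. = FALSE)
    segs <- segs[order(segs$angle_deg, decreasing = TRUE)[1:2], ]
  }
  ky <- segs[segs$convexity < 0, , drop = FALSE]
  lo <- segs[segs$convexity > 0, , drop = FALSE]
  if (nrow(ky) != 1L || nrow(lo) != 1L) {
    warning("could not assign one kyphotic and one lordotic segment by convexity",
            call. = FALSE)
    segs <- segs[order(segs$upper_y, decreasing = TRUE), ]
    ky <- segs[1L, , drop = FALSE]
    lo <- segs[2L, , drop = FALSE]
  }
  structure(list(kyphotic = ky, lordotic = lo), class = "cobb_sagittal")
}

#' @export
print.cobb_result <- function(x, ...) {
  cat(sprintf("<cobb_result> %s plane: primary %.1f deg over y [%.0f, %.0f] mm (%d segment%s)\n",
              x$plane, x$primary_angle,
              x$measurements$lower_y[x$primary],
              x$measurements$upper_y[x$primary],
              nrow(x$measurements), if (nrow(x$measurements) > 1) "s" else ""))
  invisible(x)
}

#' @export
print.cobb_sagittal <- function(x, ...) {
  cat(sprintf("<cobb_sagittal> kyphotic %.1f deg (y %.0f-%.0f), lordotic %.1f deg (y %.0f-%.0f)\n",
              x$kyphotic$angle_deg, x$kyphotic$lower_y, x$kyphotic$upper_y,
              x$lordotic$angle_deg, x$lordotic$lower_y, x$lordotic$upper_y))
  invisible(x)
}

#' Paired comparison of Cobb angles against reference readings
#'
#' Pairwise differences (measured - reference) summarized by their median and
#' interquartile range (linear-interpolation quantiles, type 7), and the
#' Pearson correlation of the two readings with its 95% confidence interval
#' (Fisher z, via [stats::cor.test()]).
#'
#' @param measured,reference equal-length numeric vectors of angles
#'   (degrees), >= 3 pairs.
#' @param conf_level confidence level (default 0.95).
#' @return list with `n`, `differences`, `median_difference`,
#'   `iqr_difference`, `r`, `conf_int`, `conf_level`.
#' @export
compare_cobb <- function(measured, reference, conf_level = 0.95) {
  measured <- as.numeric(measured); reference <- as.numeric(reference)
  if (length(measured) != length(reference))
    stop("measured and reference must be paired (equal length)", call. = FALSE)
  if (length(measured) < 3L)
    stop("at least 3 pairs are required", call. = FALSE)
  d <- measured - reference
  if (stats::sd(measured) == 0 || stats::sd(reference) == 0) {
    warning("constant angle list; correlation undefined", call. = FALSE)
    r <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    ct <- stats::cor.test(measured, reference, conf.level = conf_level)
    r <- unname(ct$estimate)
    ci <- as.numeric(ct$conf.int)
  }
  list(n = length(d), differences = d,
       median_difference = stats::median(d),
       iqr_difference = stats::IQR(d, type = 7),
       r = r, conf_int = ci, conf_level = conf_level)
}
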