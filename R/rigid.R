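# Least-squares rigid (Kabsch/SVD) registration of scanner-frame markers
# onto radiograph-frame markers, and rigid-transform utilities.

#' Proper rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 proper orthogonal matrix (R'R = I, det R = +1,
#'   checked to 1e-8).
#' @param translation 3-vector, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper orthogonal (R'R = I, det = +1)",
         call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation matrix from axis and angle (Rodrigues formula)
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_rad rotation angle in radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle_rad) {
  a <- as.numeric(axis)
  n <- sqrt(sum(a^2))
  if (n == 0) stop("axis must be non-zero", call. = FALSE)
  a <- a / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

# geodesic rotation angle, degrees
rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}

# Kabsch: proper rotation + translation minimizing sum |R s + t - t_i|^2.
# No degeneracy checks here; fit_rigid() adds them. A reflection optimum is
# corrected by flipping the smallest singular direction.
kabsch <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.numeric(ct - R %*% cs))
}

#' Fit the least-squares proper rigid transform between marker sets
#'
#' Closed-form Kabsch/SVD solution: both point sets are centred, the rotation
#' is the polar factor of their cross-covariance (reflections corrected by a
#' sign flip of the smallest singular direction), and the translation aligns
#' the centroids. Minimizes the summed squared marker distance over all proper
#' rigid transforms.
#'
#' @param source n x 3 matrix of scanner-frame marker positions (mm); marker
#'   names may be given as row names.
#' @param target n x 3 matrix of the same markers in the radiograph (EOS)
#'   frame, same row order (matched by row names when both are named).
#' @return a [rigid_transform()] mapping source onto target.
#' @details At least 3 correspondences are required and the source markers
#'   must not be collinear (smallest singular value of the centred source
#'   matrix > 1e-6 times the largest).
#' @export
fit_rigid <- function(source, target) {
  source <- as_pts3(source); target <- as_pts3(target)
  if (!is.null(rownames(source)) && !is.null(rownames(target))) {
    common <- intersect(rownames(source), rownames(target))
    if (length(common) < nrow(source) || length(common) < nrow(target)) {
      source <- source[common, , drop = FALSE]
      target <- target[common, , drop = FALSE]
    } else {
      target <- target[rownames(source), , drop = FALSE]
    }
  }
  if (nrow(source) != nrow(target))
    stop("source and target must have the same number of markers",
         call. = FALSE)
  if (nrow(source) < 3L)
    stop("degenerate geometry: at least 3 marker correspondences required",
         call. = FALSE)
  sc <- sweep(source, 2, colMeans(source))
  sv <- svd(sc)$d
  if (sv[2] < 1e-6 * sv[1])
    stop("degenerate geometry: source markers are (near-)collinear",
         call. = FALSE)
  k <- kabsch(source, target)
  rigid_transform(k$rotation, k$translation)
}

#' Apply a rigid transform to points
#'
#' Maps every point p to `R p + t`.
#'
#' @param transform a [rigid_transform()].
#' @param pts 3-vector, n x 3 matrix, or a list with a `points` component
#'   (e.g. a curve); row/column names are preserved.
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, pts) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.list(pts) && !is.null(pts$points)) {
    pts$points <- apply_transform(transform, pts$points)
    return(pts)
  }
  vec_in <- is.null(dim(pts))
  p <- as_pts3(pts)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  dimnames(out) <- dimnames(p)
  if (is.null(colnames(out))) colnames(out) <- c("x", "y", "z")
  if (vec_in && nrow(out) == 1L) out[1L, ] else out
}

#' Invert / compose rigid transforms
#'
#' `invert_transform(t)` returns the transform mapping targets back to
#' sources; `compose_transform(a, b)` returns the transform applying `b`
#' first, then `a`.
#'
#' @param transform,a,b [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  R <- t(transform$rotation)
  rigid_transform(R, as.numeric(-R %*% transform$translation))
}

#' @rdname invert_transform
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation + a$translation))
}

#' Marker discrepancy after registration
#'
#' Root-mean-square error over markers of the Euclidean residual
#' `|R s + t - target|`, together with per-marker residual magnitudes and
#' their standard deviation — the quality metrics reported after marker-based
#' registration.
#'
#' @param transform a fitted [rigid_transform()].
#' @param source,target the marker correspondences (n x 3, mm).
#' @return list with `rmse` (mm), `per_marker` (named residual magnitudes,
#'   mm) and `sd` (mm; `NA` for a single marker).
#' @export
marker_rmse <- function(transform, source, target) {
  source <- as_pts3(source); target <- as_pts3(target)
  stopifnot(nrow(source) == nrow(target))
  res <- apply_transform(transform, source) - target
  mag <- sqrt(rowSums(res^2))
  names(mag) <- rownames(source)
  list(rmse = sqrt(mean(mag^2)), per_marker = mag,
       sd = if (length(mag) > 1L) stats::sd(mag) else NA_real_)
}

#' Read / write rigid transforms as JSON
#'
#' Serialized as `{"rotation": [[...], ...], "translation": [...]}` with the
#' rotation in row-major order.
#'
#' @param path file path.
#' @return `read_transform()` returns a [rigid_transform()].
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(j$rotation, j$translation)
}

#' @rdname read_transform
#' @param transform a [rigid_transform()].
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  json_write(list(rotation = transform$rotation,
                  translation = transform$translation), path)
  invisible(path)
}
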