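# Calibrated radiograph views and 2D annotations.
#
# Shared (EOS) frame convention used throughout the package:
#   y  vertical, increasing cranially (caudal -> cranial)
#   x  lateral  (frontal-plane deviation)
#   z  antero-posterior (sagittal-plane deviation, increasing posteriorly)
# The frontal image plane is spanned by (x, y), the lateral by (z, y).

#' Calibrated biplanar radiograph view
#'
#' Describes one radiographic view (frontal or lateral) and its affine
#' pixel-to-millimetre mapping into the shared 3D coordinate system. The
#' calibration fields correspond to the DICOM tags Pixel Spacing, Image
#' Position and Rows/Columns, and are typically read from a JSON sidecar
#' (see [read_radiograph_frame()]).
#'
#' @param view `"frontal"` or `"lateral"`. The frontal view maps image axes
#'   to the (x, y) plane of the shared frame, the lateral view to (z, y).
#' @param pixel_spacing numeric length 2, mm per pixel as `c(row, col)`
#'   (DICOM Pixel Spacing order). Both components must be strictly positive.
#' @param origin_mm numeric length 3, position (mm) of pixel `(col = 0,
#'   row = 0)` in the shared frame.
#' @param image_size_px integer length 2, `c(rows, cols)`.
#' @return An object of class `radiograph_frame`.
#' @seealso [pixel_to_mm()], [mm_to_pixel()]
#' @export
radiograph_frame <- function(view = c("frontal", "lateral"),
                             pixel_spacing,
                             origin_mm,
                             image_size_px) {
  view <- match.arg(view)
  pixel_spacing <- as.numeric(pixel_spacing)
  origin_mm <- as.numeric(origin_mm)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0))
    stop("pixel_spacing must be two strictly positive values (mm/pixel)",
         call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("origin_mm must be a finite 3-vector (mm)", call. = FALSE)
  image_size_px <- as.integer(image_size_px)
  if (length(image_size_px) != 2L || any(is.na(image_size_px)) ||
      any(image_size_px < 2L))
    stop("image_size_px must be c(rows, cols), both >= 2", call. = FALSE)
  structure(
    list(view = view, pixel_spacing = pixel_spacing,
         origin_mm = origin_mm, image_size_px = image_size_px),
    class = "radiograph_frame"
  )
}

#' @export
print.radiograph_frame <- function(x, ...) {
  cat(sprintf("<radiograph_frame> %s view, %d x %d px, spacing %.4g/%.4g mm\n",
              x$view, x$image_size_px[1], x$image_size_px[2],
              x$pixel_spacing[1], x$pixel_spacing[2]))
  cat(sprintf("  origin (mm): %s\n", paste(format(x$origin_mm), collapse = ", ")))
  invisible(x)
}

# coerce a point / matrix to an n x 2 matrix
as_pts2 <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 2L)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("expected 2-column point input", call. = FALSE)
  p
}

# coerce to n x 3
as_pts3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3L)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("expected 3-column point input", call. = FALSE)
  p
}

#' Convert pixel annotations to millimetres in a view's image plane
#'
#' Applies the affine calibration of a radiograph view. The image row axis
#' points downwards in pixel space while the shared frame's y axis points
#' cranially, so rows are flipped:
#' `y = origin_y + spacing_row * (rows - 1 - row)`. The horizontal in-plane
#' coordinate is `u = origin_u + spacing_col * col`, where `u` is x for the
#' frontal view and z for the lateral view.
#'
#' @param p_px pixel point `c(col, row)` or an n x 2 matrix of them. Fractional
#'   pixel coordinates (sub-pixel picks) are allowed.
#' @param frame a [radiograph_frame()].
#' @return `(u, y)` in mm, same shape as the input (vector in, vector out).
#' @examples
#' fr <- radiograph_frame("frontal", c(0.2, 0.2), c(0, 0, 0), c(100, 100))
#' pixel_to_mm(c(50, 49), fr)  # (10, 10)
#' @export
pixel_to_mm <- function(p_px, frame) {
  stopifnot(inherits(frame, "radiograph_frame"))
  vec_in <- is.null(dim(p_px))
  p <- as_pts2(p_px)
  rows <- frame$image_size_px[1]; cols <- frame$image_size_px[2]
  bad <- !is.finite(p[, 1]) | !is.finite(p[, 2]) |
    p[, 1] < 0 | p[, 1] > cols - 1 | p[, 2] < 0 | p[, 2] > rows - 1
  if (any(bad))
    stop(sprintf("pixel coordinates outside the %s image bounds (%d x %d)",
                 frame$view, rows, cols), call. = FALSE)
  u0 <- if (frame$view == "frontal") frame$origin_mm[1] else frame$origin_mm[3]
  u <- u0 + frame$pixel_spacing[2] * p[, 1]
  y <- frame$origin_mm[2] + frame$pixel_spacing[1] * (rows - 1 - p[, 2])
  out <- cbind(u = u, y = y)
  if (vec_in && nrow(out) == 1L) out[1L, ] else out
}

#' Inverse of [pixel_to_mm()]
#'
#' @param p_mm `(u, y)` mm point or n x 2 matrix.
#' @param frame a [radiograph_frame()].
#' @return pixel coordinates `(col, row)` (fractional).
#' @export
mm_to_pixel <- function(p_mm, frame) {
  stopifnot(inherits(frame, "radiograph_frame"))
  vec_in <- is.null(dim(p_mm))
  p <- as_pts2(p_mm)
  rows <- frame$image_size_px[1]
  u0 <- if (frame$view == "frontal") frame$origin_mm[1] else frame$origin_mm[3]
  col <- (p[, 1] - u0) / frame$pixel_spacing[2]
  row <- rows - 1 - (p[, 2] - frame$origin_mm[2]) / frame$pixel_spacing[1]
  out <- cbind(col = col, row = row)
  if (vec_in && nrow(out) == 1L) out[1L, ] else out
}

#' 2D annotation set for one radiograph view
#'
#' Bundles the marker picks and the drawn internal-spinal-line (ISL) polyline
#' for one view, in pixel coordinates, together with the sidecar reference of
#' the frame they belong to and a timestamp.
#'
#' @param markers named list of `c(col, row)` picks, or a matrix with marker
#'   names as row names.
#' @param isl_px the ISL polyline drawn from C7 down to L5, as an m x 2 matrix
#'   of `(col, row)` pixel points, m >= 2.
#' @param frame_ref character, reference (e.g. sidecar file name) of the
#'   [radiograph_frame()] these picks were made on.
#' @param timestamp ISO-8601 string; defaults to the current UTC time.
#' @return An object of class `annotation2d`.
#' @export
annotation2d <- function(markers, isl_px, frame_ref,
                         timestamp = format(Sys.time(),
                                            "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) {
  if (is.list(markers) && !is.data.frame(markers)) {
    nm <- names(markers)
    markers <- do.call(rbind, lapply(markers, as.numeric))
    rownames(markers) <- nm
  }
  markers <- as.matrix(markers)
  storage.mode(markers) <- "double"
  if (ncol(markers) != 2L || is.null(rownames(markers)))
    stop("markers must be named (col, row) picks", call. = FALSE)
  isl_px <- as_pts2(isl_px)
  if (nrow(isl_px) < 2L)
    stop("isl_px must contain at least 2 points", call. = FALSE)
  structure(
    list(markers = markers, isl_px = isl_px,
         frame_ref = as.character(frame_ref),
         timestamp = as.character(timestamp)),
    class = "annotation2d"
  )
}

#' Check that an annotation lies inside its frame
#'
#' Verifies every marker pick and polyline point against the frame's pixel
#' bounds (errors on violation, invisibly returns the annotation otherwise).
#'
#' @param ann an [annotation2d()].
#' @param frame the [radiograph_frame()] the annotation refers to.
#' @export
validate_annotation <- function(ann, frame) {
  stopifnot(inherits(ann, "annotation2d"))
  pixel_to_mm(ann$markers, frame)
  pixel_to_mm(ann$isl_px, frame)
  invisible(ann)
}

## --- JSON sidecar I/O ------------------------------------------------------

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read / write radiograph frame sidecars
#'
#' Sidecars are JSON files holding the calibration fields (derived from the
#' DICOM tags Pixel Spacing, Image Position, Rows/Columns):
#' `{"view": "frontal", "pixel_spacing": [r, c], "origin_mm": [x, y, z],
#'   "image_size_px": [rows, cols]}`.
#'
#' @param path file path.
#' @return `read_radiograph_frame()` returns a [radiograph_frame()];
#'   `write_radiograph_frame()` invisibly returns `path`.
#' @export
read_radiograph_frame <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  radiograph_frame(j$view, j$pixel_spacing, j$origin_mm, j$image_size_px)
}

#' @rdname read_radiograph_frame
#' @param frame a [radiograph_frame()].
#' @export
write_radiograph_frame <- function(frame, path) {
  stopifnot(inherits(frame, "radiograph_frame"))
  json_write(unclass(frame), path)
  invisible(path)
}

#' Read / write 2D annotation files
#'
#' One JSON file per view per patient:
#' `{"frame_ref": ..., "timestamp": ..., "markers": {"C7": [col, row], ...},
#'   "isl_polyline": [[col, row], ...]}`.
#'
#' @param path file path.
#' @return `read_annotation2d()` returns an [annotation2d()].
#' @export
read_annotation2d <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- do.call(rbind, j$markers)
  annotation2d(mk, j$isl_polyline, j$frame_ref, j$timestamp)
}

#' @rdname read_annotation2d
#' @param ann an [annotation2d()].
#' @export
write_annotation2d <- function(ann, path) {
  stopifnot(inherits(ann, "annotation2d"))
  mk <- lapply(seq_len(nrow(ann$markers)), function(i) unname(ann$markers[i, ]))
  names(mk) <- rownames(ann$markers)
  json_write(list(frame_ref = ann$frame_ref, timestamp = ann$timestamp,
                  markers = mk, isl_polyline = unname(ann$isl_px)),
             path)
  invisible(path)
}
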