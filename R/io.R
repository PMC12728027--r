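# Minimal ASCII point-cloud I/O (PLY and PCD vertex clouds). Only the xyz
# vertex element is supported — back-surface scans enter this pipeline as
# bare point clouds, faces and colours are irrelevant here.

#' Write a point cloud as ASCII PLY
#'
#' @param pts n x 3 point matrix (mm).
#' @param path output file.
#' @param comment optional header comment line.
#' @return invisibly, `path`.
#' @export
write_ply <- function(pts, path, comment = NULL) {
  pts <- as_pts3(pts)
  header <- c("ply", "format ascii 1.0",
              if (!is.null(comment)) paste("comment", comment),
              sprintf("element vertex %d", nrow(pts)),
              "property float x", "property float y", "property float z",
              "end_header")
  body <- sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3])
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ASCII PLY vertex cloud
#'
#' @param path PLY file (ASCII format, xyz float vertex properties).
#' @return n x 3 matrix `(x, y, z)`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply"))
    stop("not a PLY file: ", path, call. = FALSE)
  end <- match("end_header", lines)
  if (is.na(end)) stop("PLY header not terminated", call. = FALSE)
  nline <- grep("^element vertex ", lines[seq_len(end)], value = TRUE)
  if (!length(nline)) stop("PLY file has no vertex element", call. = FALSE)
  n <- as.integer(sub("^element vertex ", "", nline[1]))
  if (any(grepl("format binary", lines[seq_len(end)])))
    stop("binary PLY is not supported; export as ASCII", call. = FALSE)
  vals <- do.call(rbind, lapply(strsplit(trimws(lines[end + seq_len(n)]), "\\s+"),
                                function(v) as.numeric(v[1:3])))
  colnames(vals) <- c("x", "y", "z")
  vals
}

#' Write a point cloud as ASCII PCD
#'
#' @param pts n x 3 point matrix (mm).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_pcd <- function(pts, path) {
  pts <- as_pts3(pts)
  n <- nrow(pts)
  header <- c("# .PCD v0.7 - Point Cloud Data file format",
              "VERSION 0.7", "FIELDS x y z", "SIZE 4 4 4", "TYPE F F F",
              "COUNT 1 1 1", sprintf("WIDTH %d", n), "HEIGHT 1",
              "VIEWPOINT 0 0 0 1 0 0 0", sprintf("POINTS %d", n),
              "DATA ascii")
  writeLines(c(header, sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3])),
             path)
  invisible(path)
}

#' Read an ASCII PCD point cloud
#'
#' @param path PCD file with `DATA ascii` and x y z fields.
#' @return n x 3 matrix `(x, y, z)`.
#' @export
read_pcd <- function(path) {
  lines <- readLines(path)
  di <- grep("^DATA", lines)[1]
  if (is.na(di)) stop("not a PCD file: ", path, call. = FALSE)
  if (!grepl("ascii", lines[di]))
    stop("binary PCD is not supported; export as ASCII", call. = FALSE)
  pl <- grep("^POINTS ", lines, value = TRUE)[1]
  n <- as.integer(sub("^POINTS ", "", pl))
  vals <- do.call(rbind, lapply(strsplit(trimws(lines[di + seq_len(n)]), "\\s+"),
                                function(v) as.numeric(v[1:3])))
  colnames(vals) <- c("x", "y", "z")
  vals
}

#' Read / write a point cloud, dispatching on file extension
#'
#' `.ply` and `.pcd` are supported; writing preserves whichever format the
#' input used.
#'
#' @param path file path ending in `.ply` or `.pcd`.
#' @return `read_point_cloud()` returns an n x 3 matrix.
#' @export
read_point_cloud <- function(path) {
  switch(tolower(tools::file_ext(path)),
         ply = read_ply(path),
         pcd = read_pcd(path),
         stop("unsupported point-cloud format: ", path, call. = FALSE))
}

#' @rdname read_point_cloud
#' @param pts n x 3 point matrix.
#' @export
write_point_cloud <- function(pts, path) {
  switch(tolower(tools::file_ext(path)),
         ply = write_ply(pts, path),
         pcd = write_pcd(pts, path),
         stop("unsupported point-cloud format: ", path, call. = FALSE))
}
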