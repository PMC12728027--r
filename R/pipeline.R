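# End-to-end batch pipeline: load a patient folder, triangulate the
# radiographic markers and ISL, register the scan bundle, correlate SPL and
# ISL shapes, compute Cobb angles, and aggregate cohort statistics.

#' Pipeline configuration
#'
#' All tunables of the processing pipeline in one place. A configuration can
#' also be read from a YAML file ([read_pipeline_config()]); unknown keys are
#' rejected.
#'
#' @param n_samples common resampling grid size for triangulated and smoothed
#'   lines (default 100).
#' @param smoothing `"auto"` (GCV-selected spline penalty) or a numeric
#'   `spar` value, see [smooth_curve()].
#' @param tangent_window_mm local-regression window for Cobb tangents
#'   (default 12), see [local_tangent()].
#' @param min_segment_mm minimum Cobb segment length (default 20), see
#'   [find_inflections()].
#' @param marker_subset character vector of marker names to register on, or
#'   `NULL` (default) for all markers present in both modalities. Use
#'   `c("C7", "L5", "PSIS_L", "PSIS_R")` to mirror the four-marker clinical
#'   protocol.
#' @param y_residual_warn_mm triangulation quality flag threshold (default 15).
#' @param quantile_type quantile rule for medians/IQRs (default 7, linear
#'   interpolation).
#' @param write_results write a `result.json` into each patient folder
#'   (default TRUE).
#' @param verbose log per-stage timings to stderr (default FALSE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_samples = 100,
                            smoothing = "auto",
                            tangent_window_mm = 12,
                            min_segment_mm = 20,
                            marker_subset = NULL,
                            y_residual_warn_mm = 15,
                            quantile_type = 7,
                            write_results = TRUE,
                            verbose = FALSE) {
  structure(list(n_samples = as.integer(n_samples), smoothing = smoothing,
                 tangent_window_mm = tangent_window_mm,
                 min_segment_mm = min_segment_mm,
                 marker_subset = marker_subset,
                 y_residual_warn_mm = y_residual_warn_mm,
                 quantile_type = as.integer(quantile_type),
                 write_results = isTRUE(write_results),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

# PCC with the degenerate-shape convention: two flat sequences are the same
# (degenerate) shape -> 1; one flat sequence has no defined correlation -> NA
pcc_or_convention <- function(pair, plane, tol = 1e-6) {
  idx <- if (plane == "frontal") 1L else 3L
  sa <- stats::sd(pair$spl[, idx]); sb <- stats::sd(pair$isl[, idx])
  if (sa < tol && sb < tol)
    return(list(value = 1, note = "both curves flat in this plane"))
  if (sa < tol || sb < tol)
    return(list(value = NA_real_,
                note = sprintf("%s curve flat in this plane",
                               if (sa < tol) "SPL" else "ISL")))
  list(value = pcc_per_plane(pair, plane), note = NULL)
}

#' Process one patient folder end-to-end
#'
#' Runs the full evaluation: reads the radiograph sidecars, annotations and
#' scan bundle; triangulates the markers and the ISL from the two views;
#' fits the rigid scanner-to-EOS transform from the marker correspondences
#' and applies it to the scan bundle; smooths SPL and ISL, superimposes the
#' ISL on the SPL by rotation+translation Procrustes, and computes the
#' per-plane Pearson shape correlations; computes frontal, kyphotic and
#' lordotic Cobb angles from the smoothed ISL. Any stage error marks the
#' patient `failed` (with the stage name) without raising, so batches
#' continue.
#'
#' Two documented conventions for degenerate spines: if SPL and ISL are both
#' flat in a plane their shape correlation is reported as 1 (identical
#' degenerate shapes; flat vs non-flat gives NA), and a straight sagittal
#' profile (single segment, angle < 1 degree) reports kyphotic = lordotic =
#' 0 instead of the single-curve error.
#'
#' @param dir patient folder (see [write_phantom()] for the layout).
#' @param config a [pipeline_config()].
#' @return list of class `patient_result`; key fields: `status`
#'   (`"processed"`/`"failed"`), `marker_rmse`, `residual_sd`,
#'   `y_residuals`, `transform`, `pcc_frontal`, `pcc_sagittal`,
#'   `procrustes_disparity`, `cobb_frontal_primary`, `cobb_kyphotic`,
#'   `cobb_lordotic`, `segments`.
#' @export
process_patient <- function(dir, config = pipeline_config()) {
  stage <- "load"
  t0 <- proc.time()[3]
  log_stage <- function(what) {
    if (config$verbose)
      message(sprintf("[%s] %-12s %6.2f s", basename(dir), what,
                      proc.time()[3] - t0))
  }
  res <- tryCatch({
    need <- c("radiograph_frontal.json", "radiograph_lateral.json",
              "annotation_frontal.json", "annotation_lateral.json",
              "scan_markers.json", "scan_spl.json")
    missing <- need[!file.exists(file.path(dir, need))]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    fr_f <- read_radiograph_frame(file.path(dir, "radiograph_frontal.json"))
    fr_l <- read_radiograph_frame(file.path(dir, "radiograph_lateral.json"))
    an_f <- read_annotation2d(file.path(dir, "annotation_frontal.json"))
    an_l <- read_annotation2d(file.path(dir, "annotation_lateral.json"))
    validate_annotation(an_f, fr_f)
    validate_annotation(an_l, fr_l)
    mk <- jsonlite::read_json(file.path(dir, "scan_markers.json"),
                              simplifyVector = TRUE)
    scan_markers <- do.call(rbind, mk)
    scan_spl <- as_pts3(jsonlite::read_json(file.path(dir, "scan_spl.json"),
                                            simplifyVector = TRUE))
    surface_file <- Filter(file.exists,
                           file.path(dir, c("surface.ply", "surface.pcd")))
    scan_surface <- if (length(surface_file))
      read_point_cloud(surface_file[1]) else NULL
    log_stage("load")

    stage <- "triangulate"
    tri <- triangulate_markers(an_f, fr_f, an_l, fr_l,
                               config$y_residual_warn_mm)
    isl3d <- triangulate_polyline(pixel_to_mm(an_f$isl_px, fr_f),
                                  pixel_to_mm(an_l$isl_px, fr_l),
                                  config$n_samples)
    log_stage("triangulate")

    stage <- "register"
    use <- intersect(rownames(scan_markers), rownames(tri$points))
    if (!is.null(config$marker_subset))
      use <- intersect(use, config$marker_subset)
    transform <- fit_rigid(scan_markers[use, , drop = FALSE],
                           tri$points[use, , drop = FALSE])
    err <- marker_rmse(transform, scan_markers[use, , drop = FALSE],
                       tri$points[use, , drop = FALSE])
    spl_eos <- apply_transform(transform, scan_spl)
    surface_eos <- if (is.null(scan_surface)) NULL else
      apply_transform(transform, scan_surface)
    log_stage("register")

    stage <- "smooth"
    spl_curve <- smooth_curve(spl_eos, config$smoothing, config$n_samples,
                              label = "SPL")
    isl_curve <- smooth_curve(isl3d, config$smoothing, config$n_samples,
                              label = "ISL")
    log_stage("smooth")

    stage <- "correlate"
    pair <- pair_curves(spl_curve, isl_curve, config$n_samples)
    alignment <- procrustes_align(pair$spl, pair$isl)
    pair$isl <- alignment$points
    pf <- pcc_or_convention(pair, "frontal")
    ps <- pcc_or_convention(pair, "sagittal")
    log_stage("correlate")

    stage <- "cobb"
    cf <- cobb_frontal(isl_curve, config$tangent_window_mm,
                       config$min_segment_mm)
    sag <- tryCatch(
      cobb_sagittal(isl_curve, config$tangent_window_mm,
                    config$min_segment_mm),
      error = function(e) e
    )
    sag_note <- NULL
    if (inherits(sag, "error")) {
      one <- cobb_segments(isl_curve, "sagittal", config$tangent_window_mm,
                           config$min_segment_mm)
      if (nrow(one) == 1L && one$angle_deg < 1) {
        ky <- 0; lo <- 0
        sag_note <- "straight sagittal profile; angles set to 0"
      } else {
        ky <- NA_real_; lo <- NA_real_
        sag_note <- conditionMessage(sag)
      }
    } else {
      ky <- sag$kyphotic$angle_deg
      lo <- sag$lordotic$angle_deg
    }
    log_stage("cobb")

    out <- list(
      patient_id = basename(normalizePath(dir)),
      status = "processed", failed_stage = NULL,
      timestamps = list(frontal = an_f$timestamp, lateral = an_l$timestamp),
      markers_used = use,
      markers_3d = tri$points,
      y_residuals = tri$y_residuals,
      transform = transform,
      marker_rmse = err$rmse, residual_sd = err$sd,
      per_marker_residuals = err$per_marker,
      n_common = pair$n,
      procrustes_disparity = alignment$disparity,
      pcc_frontal = pf$value, pcc_sagittal = ps$value,
      pcc_notes = c(pf$note, ps$note),
      cobb_frontal_primary = cf$primary_angle,
      cobb_kyphotic = ky, cobb_lordotic = lo,
      sagittal_note = sag_note,
      segments = cf$measurements,
      surface_points = if (is.null(surface_eos)) 0L else nrow(surface_eos)
    )
    class(out) <- "patient_result"
    out
  }, error = function(e) {
    structure(list(patient_id = basename(normalizePath(dir)),
                   status = "failed", failed_stage = stage,
                   error = conditionMessage(e)),
              class = "patient_result")
  })
  if (config$write_results && res$status == "processed")
    write_patient_result(res, file.path(dir, "result.json"))
  res
}

#' @export
print.patient_result <- function(x, ...) {
  if (x$status == "failed") {
    cat(sprintf("<patient_result> %s FAILED at stage '%s': %s\n",
                x$patient_id, x$failed_stage, x$error))
  } else {
    cat(sprintf(
      "<patient_result> %s: RMSE %.2f mm, PCC %.3f/%.3f (frontal/sagittal), Cobb %.1f/%.1f/%.1f deg (frontal/kyphotic/lordotic)\n",
      x$patient_id, x$marker_rmse, x$pcc_frontal, x$pcc_sagittal,
      x$cobb_frontal_primary, x$cobb_kyphotic, x$cobb_lordotic))
  }
  invisible(x)
}

write_patient_result <- function(res, path) {
  out <- res[c("patient_id", "status", "timestamps", "markers_used",
               "marker_rmse", "residual_sd", "n_common",
               "procrustes_disparity", "pcc_frontal", "pcc_sagittal",
               "cobb_frontal_primary", "cobb_kyphotic", "cobb_lordotic")]
  out$y_residuals <- as.list(res$y_residuals)
  out$per_marker_residuals <- as.list(res$per_marker_residuals)
  out$transform <- list(rotation = res$transform$rotation,
                        translation = res$transform$translation)
  out$segments <- res$segments
  json_write(out, path)
  invisible(path)
}

#' Locate patient folders under a root directory
#'
#' A patient folder is any direct subdirectory containing
#' `annotation_frontal.json`.
#'
#' @param root parent directory.
#' @return character vector of patient folder paths.
#' @export
find_patient_dirs <- function(root) {
  dirs <- list.dirs(root, recursive = FALSE)
  dirs[file.exists(file.path(dirs, "annotation_frontal.json"))]
}

#' Batch-process a cohort of patient folders
#'
#' Runs [process_patient()] over every folder; failures are recorded, not
#' raised.
#'
#' @param dirs character vector of patient folders, or a single root
#'   directory (searched with [find_patient_dirs()]).
#' @param config a [pipeline_config()].
#' @return named list of `patient_result`s.
#' @export
batch_process <- function(dirs, config = pipeline_config()) {
  if (length(dirs) == 1L && dir.exists(dirs) &&
      !file.exists(file.path(dirs, "annotation_frontal.json"))) {
    dirs <- find_patient_dirs(dirs)
  }
  if (!length(dirs)) stop("no patient folders found", call. = FALSE)
  res <- lapply(dirs, process_patient, config = config)
  names(res) <- vapply(res, function(r) r$patient_id, character(1))
  res
}

#' Cohort summary statistics
#'
#' Medians and interquartile ranges (type-7 linear-interpolation quantiles by
#' default) of the per-patient quality metrics and angles over all processed
#' patients; failed patients are excluded and counted.
#'
#' @param results list of `patient_result`s from [batch_process()].
#' @param quantile_type quantile rule (default 7).
#' @return list of class `cohort_summary` with a `metrics` data.frame
#'   (median, IQR, n per metric), `n_processed`, `n_failed`, `failed_stages`.
#' @export
summarize_cohort <- function(results, quantile_type = 7) {
  ok <- Filter(function(r) identical(r$status, "processed"), results)
  failed <- Filter(function(r) !identical(r$status, "processed"), results)
  if (!length(ok)) stop("empty cohort: no processed patients", call. = FALSE)
  fields <- c(marker_rmse = "marker_rmse", residual_sd = "residual_sd",
              pcc_frontal = "pcc_frontal", pcc_sagittal = "pcc_sagittal",
              cobb_frontal = "cobb_frontal_primary",
              cobb_kyphotic = "cobb_kyphotic", cobb_lordotic = "cobb_lordotic")
  grab <- function(f) vapply(ok, function(r) {
    v <- r[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  med <- function(v) stats::quantile(v, 0.5, type = quantile_type,
                                     na.rm = TRUE, names = FALSE)
  iqr <- function(v) diff(stats::quantile(v, c(0.25, 0.75),
                                          type = quantile_type,
                                          na.rm = TRUE, names = FALSE))
  metrics <- do.call(rbind, lapply(names(fields), function(nm) {
    v <- grab(fields[[nm]])
    data.frame(metric = nm, median = med(v), iqr = iqr(v),
               n = sum(!is.na(v)))
  }))
  structure(list(metrics = metrics, n_processed = length(ok),
                 n_failed = length(failed),
                 failed_stages = vapply(failed, function(r) r$failed_stage,
                                        character(1)),
                 quantile_type = quantile_type),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d processed, %d failed\n",
              x$n_processed, x$n_failed))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-14s median %8.3f  IQR %8.3f  (n = %d)\n",
                m$metric[i], m$median[i], m$iqr[i], m$n[i]))
  invisible(x)
}
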