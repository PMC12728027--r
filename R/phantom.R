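# Synthetic patient phantoms with closed-form ground truth.
#
# A phantom emulates one acquisition: a parametric internal spinal line (ISL)
# from L5 (y = 0) to C7 (y = spine_length), a skin-level spinous process line
# (SPL) that follows the ISL with damped frontal amplitude and a posterior
# depth offset, nine skin markers, the two calibrated radiograph views with
# their pixel annotations, and a surface patch + markers + SPL "scan bundle"
# expressed in a scanner frame related to the radiographic (EOS) frame by a
# known rigid postural transform. Every stochastic element is driven by the
# phantom seed.
#
# Curve construction gives analytic truth:
#  * frontal "sine" mode: x(y) = A sin(2*pi*y/lambda) — scoliotic S-curve;
#  * frontal "arc" mode and the sagittal profile: circular arcs, whose Cobb
#    angle (angle between boundary tangents) equals the subtended arc angle
#    exactly. The sagittal profile is two tangent-continuous arcs of opposite
#    curvature joined at the thoracolumbar junction, subtending exactly the
#    requested kyphotic and lordotic angles.

# one circular-arc coordinate profile on [y0, y1] with tangent angle psi0 at
# y0 and psi1 at y1 (radians, |psi| < pi/2); value fixed at `v` at y = yref.
# Signed radius R > 0 gives d2z/dy2 > 0 (anteriorly convex with z posterior).
arc_segment <- function(y0, y1, psi0, psi1, yref, vref = 0) {
  R <- (y1 - y0) / (sin(psi1) - sin(psi0))
  yc <- y0 - R * sin(psi0)
  f0 <- function(y) {
    s <- (y - yc) / R
    -R * sqrt(pmax(0, 1 - s^2))
  }
  off <- vref - f0(yref)
  list(
    f = function(y) f0(y) + off,
    d1 = function(y) {
      s <- (y - yc) / R
      s / sqrt(pmax(1e-12, 1 - s^2))
    },
    d2 = function(y) {
      s <- (y - yc) / R
      1 / (R * pmax(1e-12, 1 - s^2)^1.5)
    },
    R = R, yc = yc
  )
}

# Sagittal double-curve profile: lordotic (z'' > 0) segment on [0, yj],
# kyphotic (z'' < 0) segment on [yj, L], C2-smooth throughout. The tangent
# slope follows a raised-cosine between the three prescribed values s(0),
# s(yj), s(L), so the curvature vanishes at both curve ends and crosses zero
# transversally only at the junction; the tilt is extremal exactly at the
# endpoints and the junction, and the angles between the boundary tangents
# equal the requested kyphotic/lordotic Cobb angles in closed form.
sagittal_profile <- function(kyphosis_deg, lordosis_deg, L, junction_frac = 0.4) {
  if (kyphosis_deg == 0 && lordosis_deg == 0) {
    zero <- function(y) rep(0, length(y))
    return(list(f = zero, d1 = zero, d2 = zero, yj = NA_real_))
  }
  if (kyphosis_deg <= 0 || lordosis_deg <= 0)
    stop("kyphosis and lordosis angles must both be positive (or both zero)",
         call. = FALSE)
  th_k <- kyphosis_deg * pi / 180
  th_l <- lordosis_deg * pi / 180
  psi_j <- th_k / 2                      # shared tangent angle at the junction
  yj <- junction_frac * L
  H <- L - yj
  s0 <- tan(psi_j - th_l)                # tangent slope at L5 (y = 0)
  sj <- tan(psi_j)                       # at the thoracolumbar junction
  sL <- tan(psi_j - th_k)                # at C7 (y = L)
  f_lo <- function(y) s0 * y +
    (sj - s0) / 2 * (y - (yj / pi) * sin(pi * y / yj))
  zj <- f_lo(yj)
  list(
    f = function(y) {
      u <- y - yj
      ifelse(y <= yj,
             f_lo(pmax(y, 0)),
             zj + sL * u + (sj - sL) / 2 * (u + (H / pi) * sin(pi * u / H)))
    },
    d1 = function(y) {
      u <- y - yj
      ifelse(y <= yj,
             s0 + (sj - s0) * (1 - cos(pi * y / yj)) / 2,
             sL + (sj - sL) * (1 + cos(pi * u / H)) / 2)
    },
    d2 = function(y) {
      u <- y - yj
      ifelse(y <= yj,
             (sj - s0) * pi / (2 * yj) * sin(pi * y / yj),
             -(sj - sL) * pi / (2 * H) * sin(pi * u / H))
    },
    yj = yj
  )
}

# frontal profile: sine S-curve or single circular arc C-curve
frontal_profile <- function(mode, amplitude, wavelength, arc_angle_deg, L) {
  if (mode == "sine") {
    k <- 2 * pi / wavelength
    list(
      f = function(y) amplitude * sin(k * y),
      d1 = function(y) amplitude * k * cos(k * y),
      d2 = function(y) -amplitude * k^2 * sin(k * y),
      mode = "sine", k = k, amplitude = amplitude
    )
  } else {
    if (is.null(arc_angle_deg) || arc_angle_deg <= 0)
      stop("arc mode requires a positive frontal_arc_angle_deg", call. = FALSE)
    th <- arc_angle_deg * pi / 180
    a <- arc_segment(0, L, -th / 2, th / 2, yref = 0)
    c(a[c("f", "d1", "d2")], list(mode = "arc", angle_deg = arc_angle_deg))
  }
}

# analytic frontal Cobb: tangents at interior inflections + endpoints
frontal_truth_cobb <- function(fp, L, min_segment_mm = 20) {
  if (fp$mode == "arc")
    return(list(primary = fp$angle_deg,
                segments = data.frame(lower_y = 0, upper_y = L,
                                      angle_deg = fp$angle_deg)))
  if (fp$amplitude == 0)
    return(list(primary = 0,
                segments = data.frame(lower_y = 0, upper_y = L, angle_deg = 0)))
  lambda <- 2 * pi / fp$k
  m <- seq_len(floor(2 * L / lambda + 1))
  interior <- m * lambda / 2
  interior <- interior[interior > min_segment_mm & interior < L - min_segment_mm]
  anchors <- c(0, interior, L)
  sl <- fp$d1(anchors)
  ang <- abs(diff(atan(sl))) * 180 / pi
  list(primary = max(ang),
       segments = data.frame(lower_y = anchors[-length(anchors)],
                             upper_y = anchors[-1], angle_deg = ang))
}

#' Specification of one synthetic patient phantom
#'
#' Defaults describe a mid-cohort scoliotic adolescent: a single-S frontal
#' curve of about 29 degrees Cobb over a 450 mm C7-L5 span, kyphosis ~41 and
#' lordosis ~40 degrees, skin line 35 mm posterior to the vertebral line with
#' 0.55 frontal amplitude damping.
#'
#' @param frontal_mode `"sine"` (S-curve) or `"arc"` (single C-curve).
#' @param frontal_amplitude_mm sine amplitude A (mm); ignored in arc mode.
#' @param frontal_wavelength_mm sine wavelength (mm); defaults to the spine
#'   length (one full S between C7 and L5).
#' @param frontal_arc_angle_deg subtended angle of the C-curve (arc mode).
#' @param kyphosis_angle_deg,lordosis_angle_deg target sagittal Cobb angles
#'   (degrees); both zero gives a flat sagittal profile.
#' @param spine_length_mm C7-L5 span (default 450).
#' @param junction_frac thoracolumbar junction as a fraction of the span
#'   (default 0.4, measured from L5).
#' @param spl_offset_mm posterior skin-to-spine depth offset (default 35).
#' @param spl_damping frontal amplitude ratio SPL/ISL (default 0.55).
#' @param spl_shift_mm amplitude of a smooth transverse skin shift added to
#'   the SPL so the frontal shapes are strongly but not perfectly correlated
#'   (default 3).
#' @param marker_noise_sd_mm isotropic per-coordinate Gaussian noise on the
#'   scanner-side marker picks (default 0).
#' @param surface_noise_sd_mm Gaussian noise on the surface points (default 0).
#' @param surface_spacing_mm grid spacing of the surface patch (default 4.5,
#'   about 5 points per cm^2).
#' @param postural_transform [rigid_transform()] mapping the scanner frame to
#'   the radiographic (EOS) frame (default identity).
#' @param seed integer; fully determines all stochastic output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(frontal_mode = c("sine", "arc"),
                         frontal_amplitude_mm = 9.3,
                         frontal_wavelength_mm = NULL,
                         frontal_arc_angle_deg = NULL,
                         kyphosis_angle_deg = 41,
                         lordosis_angle_deg = 40,
                         spine_length_mm = 450,
                         junction_frac = 0.4,
                         spl_offset_mm = 35,
                         spl_damping = 0.55,
                         spl_shift_mm = 3,
                         marker_noise_sd_mm = 0,
                         surface_noise_sd_mm = 0,
                         surface_spacing_mm = 4.5,
                         postural_transform = rigid_transform(),
                         seed = 1L) {
  frontal_mode <- match.arg(frontal_mode)
  if (is.null(frontal_wavelength_mm)) frontal_wavelength_mm <- spine_length_mm
  stopifnot(spine_length_mm > 0, frontal_amplitude_mm >= 0,
            frontal_wavelength_mm > 0, marker_noise_sd_mm >= 0,
            surface_noise_sd_mm >= 0, kyphosis_angle_deg >= 0,
            lordosis_angle_deg >= 0, spl_damping >= 0,
            inherits(postural_transform, "rigid_transform"))
  structure(
    list(frontal_mode = frontal_mode,
         frontal_amplitude_mm = frontal_amplitude_mm,
         frontal_wavelength_mm = frontal_wavelength_mm,
         frontal_arc_angle_deg = frontal_arc_angle_deg,
         kyphosis_angle_deg = kyphosis_angle_deg,
         lordosis_angle_deg = lordosis_angle_deg,
         spine_length_mm = spine_length_mm,
         junction_frac = junction_frac,
         spl_offset_mm = spl_offset_mm,
         spl_damping = spl_damping,
         spl_shift_mm = spl_shift_mm,
         marker_noise_sd_mm = marker_noise_sd_mm,
         surface_noise_sd_mm = surface_noise_sd_mm,
         surface_spacing_mm = surface_spacing_mm,
         postural_transform = postural_transform,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# default calibrated views large enough for any cohort phantom
default_frames <- function(L) {
  list(
    frontal = radiograph_frame("frontal", c(0.5, 0.5),
                               c(-250, -150, 0), c(round((L + 300) / 0.5), 1000)),
    lateral = radiograph_frame("lateral", c(0.5, 0.5),
                               c(0, -150, -250), c(round((L + 300) / 0.5), 1000))
  )
}

# nine skin markers given skin-line coordinate functions
phantom_markers <- function(xs, zs, L) {
  at <- function(f) c(xs(f * L), f * L, zs(f * L))
  m <- rbind(
    C7      = at(1),
    L5      = at(0),
    PSIS_L  = c(-45, -60, zs(0) - 10),
    PSIS_R  = c( 45, -60, zs(0) - 10),
    T7      = at(0.55),
    SCAP_L  = c(-85, 0.75 * L, zs(0.75 * L) - 10),
    SCAP_R  = c( 85, 0.75 * L, zs(0.75 * L) - 10),
    FLANK_L = c(-95, 0.33 * L, zs(0.33 * L) - 15),
    FLANK_R = c( 95, 0.33 * L, zs(0.33 * L) - 15)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

#' Generate one synthetic patient
#'
#' Builds the exact spinal lines and marker layout, projects them into the
#' two calibrated radiograph views (pixel annotations), and emits the scan
#' bundle (markers, SPL, surface patch) in the scanner frame obtained by the
#' inverse postural transform, with seeded Gaussian noise on the scanner
#' marker picks and the surface points.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom` with components `spec`, `truth` (exact
#'   lines, markers in both frames, analytic Cobb angles, the postural
#'   transform, and the closed-form coordinate functions), `frames`,
#'   `annotations` (frontal/lateral [annotation2d()]), and `scan`
#'   (`markers`, `spl`, `surface`, all in the scanner frame).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  L <- spec$spine_length_mm
  sag <- sagittal_profile(spec$kyphosis_angle_deg, spec$lordosis_angle_deg,
                          L, spec$junction_frac)
  fro <- frontal_profile(spec$frontal_mode, spec$frontal_amplitude_mm,
                         spec$frontal_wavelength_mm,
                         spec$frontal_arc_angle_deg, L)
  isl_x <- fro$f; isl_z <- sag$f
  spl_x <- function(y) spec$spl_damping * isl_x(y) +
    spec$spl_shift_mm * sin(pi * y / L)
  spl_z <- function(y) isl_z(y) + spec$spl_offset_mm

  ys <- seq(0, L, length.out = 60)
  isl <- cbind(x = isl_x(ys), y = ys, z = isl_z(ys))
  spl <- cbind(x = spl_x(ys), y = ys, z = spl_z(ys))
  markers <- phantom_markers(spl_x, spl_z, L)
  frames <- default_frames(L)

  # radiograph annotations: exact projections, drawn cranial -> caudal
  proj_m <- project_to_views(markers)
  top_down <- order(ys, decreasing = TRUE)
  proj_isl <- project_to_views(isl[top_down, , drop = FALSE])
  px <- function(p2, fr) {
    out <- mm_to_pixel(p2, fr)
    rownames(out) <- rownames(p2)
    out
  }
  stamp <- "2026-01-01T00:00:00Z"   # fixed: outputs are seed-determined
  ann_f <- annotation2d(px(proj_m$frontal, frames$frontal),
                        px(proj_isl$frontal, frames$frontal),
                        frame_ref = "radiograph_frontal.json",
                        timestamp = stamp)
  ann_l <- annotation2d(px(proj_m$lateral, frames$lateral),
                        px(proj_isl$lateral, frames$lateral),
                        frame_ref = "radiograph_lateral.json",
                        timestamp = stamp)

  # surface patch: bicubic-like sheet around the SPL with mild transverse
  # curvature (flanks fall anteriorly), in the EOS frame first
  gy <- seq(0, L, by = spec$surface_spacing_mm)
  gx <- seq(-60, 60, by = spec$surface_spacing_mm)
  grid <- expand.grid(dx = gx, y = gy)
  surf <- cbind(x = spl_x(grid$y) + grid$dx,
                y = grid$y,
                z = spl_z(grid$y) - 15 * (grid$dx / 60)^2)

  # scanner frame = inverse postural transform of the EOS-frame objects
  inv <- invert_transform(spec$postural_transform)
  scan_markers_exact <- apply_transform(inv, markers)
  scan_markers <- scan_markers_exact
  if (spec$marker_noise_sd_mm > 0)
    scan_markers <- scan_markers +
      matrix(stats::rnorm(length(markers), sd = spec$marker_noise_sd_mm),
             nrow(markers), 3L)
  scan_spl <- apply_transform(inv, spl)
  if (spec$surface_noise_sd_mm > 0)
    surf <- surf + matrix(stats::rnorm(length(surf),
                                       sd = spec$surface_noise_sd_mm),
                          nrow(surf), 3L)
  scan_surface <- apply_transform(inv, surf)

  truth <- list(
    isl = isl, spl = spl,
    markers_eos = markers, markers_scanner = scan_markers_exact,
    cobb_frontal = frontal_truth_cobb(fro, L),
    cobb_kyphotic = spec$kyphosis_angle_deg,
    cobb_lordotic = spec$lordosis_angle_deg,
    sagittal_junction_y = sag$yj,
    postural_transform = spec$postural_transform,
    funs = list(isl_x = isl_x, isl_z = isl_z, isl_dx = fro$d1,
                isl_dz = sag$d1, spl_x = spl_x, spl_z = spl_z)
  )
  structure(list(spec = spec, truth = truth, frames = frames,
                 annotations = list(frontal = ann_f, lateral = ann_l),
                 scan = list(markers = scan_markers, spl = scan_spl,
                             surface = scan_surface)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> seed %d: frontal Cobb %.1f deg, kyphosis %.0f, lordosis %.0f, %d surface pts\n",
              x$spec$seed, x$truth$cobb_frontal$primary,
              x$truth$cobb_kyphotic, x$truth$cobb_lordotic,
              nrow(x$scan$surface)))
  invisible(x)
}

#' Write a phantom as an on-disk patient folder
#'
#' Produces exactly the layout [process_patient()] consumes: the two
#' radiograph sidecars and annotation files, the scan bundle
#' (`scan_markers.json`, `scan_spl.json`, `surface.ply`), and the ground
#' truth as `truth.json` (ignored by the pipeline by naming convention).
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir patient folder to create.
#' @return invisibly, `dir`.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_radiograph_frame(phantom$frames$frontal, p("radiograph_frontal.json"))
  write_radiograph_frame(phantom$frames$lateral, p("radiograph_lateral.json"))
  write_annotation2d(phantom$annotations$frontal, p("annotation_frontal.json"))
  write_annotation2d(phantom$annotations$lateral, p("annotation_lateral.json"))
  mk <- phantom$scan$markers
  mkl <- lapply(seq_len(nrow(mk)), function(i) unname(mk[i, ]))
  names(mkl) <- rownames(mk)
  json_write(mkl, p("scan_markers.json"))
  json_write(unname(as.matrix(phantom$scan$spl)), p("scan_spl.json"))
  write_ply(phantom$scan$surface, p("surface.ply"),
            comment = "synthetic back-surface patch")
  tr <- phantom$truth
  json_write(list(
    synthetic = TRUE,
    isl = unname(tr$isl), spl = unname(tr$spl),
    markers_eos = mkl_named(tr$markers_eos),
    markers_scanner = mkl_named(tr$markers_scanner),
    cobb_frontal_primary = tr$cobb_frontal$primary,
    cobb_kyphotic = tr$cobb_kyphotic,
    cobb_lordotic = tr$cobb_lordotic,
    postural_transform = list(rotation = tr$postural_transform$rotation,
                              translation = tr$postural_transform$translation)
  ), p("truth.json"))
  invisible(dir)
}

mkl_named <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  names(out) <- rownames(m)
  out
}

#' Read a phantom folder's ground truth
#'
#' @param dir patient folder written by [write_phantom()].
#' @return list with the truth fields (lines, markers, analytic Cobb angles,
#'   postural transform).
#' @export
read_phantom_truth <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  j$postural_transform <- rigid_transform(j$postural_transform$rotation,
                                          j$postural_transform$translation)
  j$markers_eos <- do.call(rbind, j$markers_eos)
  j$markers_scanner <- do.call(rbind, j$markers_scanner)
  j
}

#' Default cohort parameter ranges
#'
#' Sampling ranges emulating the descriptives of a 30-patient adolescent
#' idiopathic scoliosis cohort: frontal Cobb angles drawn as
#' `9 + 45 * Beta(1.2, 1.5)` degrees (median close to 29, range 9-54),
#' kyphosis 25-55, lordosis 25-50 degrees, spine length 400-480 mm, frontal
#' damping 0.45-0.65, postural offsets of 5-20 degrees about a random axis
#' with translations up to +/-500 mm per axis, and 2 mm scanner marker-pick
#' noise.
#'
#' @return named list of ranges consumed by [generate_cohort()].
#' @export
cohort_ranges <- function() {
  list(frontal_cobb_range = c(9, 54), frontal_cobb_shape = c(1.2, 1.5),
       kyphosis = c(25, 55), lordosis = c(25, 50),
       spine_length = c(400, 480), damping = c(0.45, 0.65),
       rotation_deg = c(5, 20), translation_mm = 500,
       marker_noise_sd_mm = 2, surface_noise_sd_mm = 0.5,
       surface_spacing_mm = 4.5)
}

#' Generate a synthetic cohort
#'
#' Samples `n` phantom specifications from the given ranges (see
#' [cohort_ranges()]) and generates each phantom. Fully deterministic under
#' `seed`: the cohort seed drives both the parameter draws and the
#' per-phantom seeds.
#'
#' @param n number of patients (>= 1).
#' @param ranges parameter ranges, defaults to [cohort_ranges()]. Individual
#'   entries may be overridden.
#' @param seed integer cohort seed.
#' @return list of class `phantom_cohort` of [generate_phantom()] results.
#' @export
generate_cohort <- function(n, ranges = cohort_ranges(), seed = 1L) {
  stopifnot(n >= 1)
  base <- cohort_ranges()
  base[names(ranges)] <- ranges
  ranges <- base
  set.seed(seed)
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    cobb <- ranges$frontal_cobb_range[1] +
      diff(ranges$frontal_cobb_range) *
      stats::rbeta(1, ranges$frontal_cobb_shape[1], ranges$frontal_cobb_shape[2])
    L <- stats::runif(1, ranges$spine_length[1], ranges$spine_length[2])
    lambda <- L                                  # one full S across the span
    A <- tan(cobb * pi / 360) * lambda / (2 * pi)
    axis <- stats::rnorm(3)
    ang <- stats::runif(1, ranges$rotation_deg[1], ranges$rotation_deg[2]) * pi / 180
    tr <- stats::runif(3, -ranges$translation_mm, ranges$translation_mm)
    spec <- phantom_spec(
      frontal_mode = "sine",
      frontal_amplitude_mm = A,
      frontal_wavelength_mm = lambda,
      kyphosis_angle_deg = stats::runif(1, ranges$kyphosis[1], ranges$kyphosis[2]),
      lordosis_angle_deg = stats::runif(1, ranges$lordosis[1], ranges$lordosis[2]),
      spine_length_mm = L,
      spl_damping = stats::runif(1, ranges$damping[1], ranges$damping[2]),
      marker_noise_sd_mm = ranges$marker_noise_sd_mm,
      surface_noise_sd_mm = ranges$surface_noise_sd_mm,
      surface_spacing_mm = ranges$surface_spacing_mm,
      postural_transform = rigid_transform(rotation_axis_angle(axis, ang), tr),
      seed = sample.int(2^30, 1)
    )
    phantoms[[i]] <- generate_phantom(spec)
  }
  structure(phantoms, class = "phantom_cohort")
}

#' Write a whole cohort as patient folders
#'
#' @param cohort a [generate_cohort()] result.
#' @param root parent directory; patients are written as `patient_01`, ...
#' @return invisibly, the patient directories.
#' @export
write_cohort <- function(cohort, root) {
  dirs <- file.path(root, sprintf("patient_%02d", seq_along(cohort)))
  for (i in seq_along(cohort)) write_phantom(cohort[[i]], dirs[i])
  invisible(dirs)
}
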