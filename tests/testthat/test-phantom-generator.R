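# Synthetic phantom generator: ground-truth consistency, determinism, and
# end-to-end recovery.

null_spec <- function(seed = 1) {
  phantom_spec(frontal_amplitude_mm = 0, kyphosis_angle_deg = 0,
               lordosis_angle_deg = 0, spl_shift_mm = 0, seed = seed)
}

test_that("the null phantom runs the whole pipeline to its degenerate fixed point", {
  ph <- generate_phantom(null_spec())
  d <- withr::local_tempdir()
  write_phantom(ph, d)
  r <- process_patient(d, pipeline_config(write_results = FALSE))
  expect_identical(r$status, "processed")
  expect_lt(r$marker_rmse, 1e-9)
  expect_identical(r$pcc_frontal, 1)
  expect_identical(r$pcc_sagittal, 1)
  expect_lt(r$cobb_frontal_primary, 0.1)
  expect_identical(r$cobb_kyphotic, 0)
  expect_identical(r$cobb_lordotic, 0)
})

test_that("phantom generation is byte-deterministic under its seed", {
  spec <- phantom_spec(seed = 42, marker_noise_sd_mm = 2,
                       surface_noise_sd_mm = 0.5)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$scan, p2$scan)
  expect_identical(p1$annotations, p2$annotations)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_phantom(p1, d1); write_phantom(p2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = paste("file", f))
  }
  # a different seed changes the noise realization
  p3 <- generate_phantom(phantom_spec(seed = 43, marker_noise_sd_mm = 2,
                                      surface_noise_sd_mm = 0.5))
  expect_false(identical(p3$scan$markers, p1$scan$markers))
})

test_that("analytic phantom Cobb angles agree with the dense numerical oracle", {
  specs <- list(
    phantom_spec(frontal_amplitude_mm = 12, kyphosis_angle_deg = 48,
                 lordosis_angle_deg = 35, seed = 1),
    phantom_spec(frontal_amplitude_mm = 25, spine_length_mm = 420,
                 kyphosis_angle_deg = 30, lordosis_angle_deg = 50, seed = 2)
  )
  for (sp in specs) {
    ph <- generate_phantom(sp)
    L <- sp$spine_length_mm
    of <- cobb_oracle_dense(ph$truth$funs$isl_x, 0, L)
    expect_lt(abs(ph$truth$cobb_frontal$primary - of$primary), 0.1)
    os <- cobb_oracle_dense(ph$truth$funs$isl_z, 0, L)
    expect_length(os$angles, 2)
    # caudal segment is the lordotic one, cranial the kyphotic one
    expect_lt(abs(ph$truth$cobb_lordotic - os$angles[1]), 0.1)
    expect_lt(abs(ph$truth$cobb_kyphotic - os$angles[2]), 0.1)
  }
})

test_that("a noiseless phantom pipeline recovers transform, angles and shape correlation", {
  tf <- rigid_transform(rotation_axis_angle(c(0.3, 1, -0.2), 0.25),
                        c(320, -150, 90))
  ph <- generate_phantom(phantom_spec(seed = 6, postural_transform = tf))
  d <- withr::local_tempdir()
  write_phantom(ph, d)
  r <- process_patient(d, pipeline_config(write_results = FALSE))
  rot_err <- acos(min(1, (sum(diag(t(r$transform$rotation) %*% tf$rotation)) - 1) / 2))
  expect_lt(rot_err, 1e-6)                           # radians
  expect_lt(max(abs(r$transform$translation - tf$translation)), 1e-3)
  expect_lt(abs(r$cobb_frontal_primary - ph$truth$cobb_frontal$primary), 1)
  expect_lt(abs(r$cobb_kyphotic - ph$truth$cobb_kyphotic), 1)
  expect_lt(abs(r$cobb_lordotic - ph$truth$cobb_lordotic), 1)
  # reference PCC from the exact construction lines via the same shape metric
  ref_spl <- smooth_curve(ph$truth$spl, "auto", 100)
  ref_isl <- smooth_curve(ph$truth$isl, "auto", 100)
  pair <- pair_curves(ref_spl, ref_isl, 100)
  pair$isl <- procrustes_align(pair$spl, pair$isl)$points
  expect_equal(r$pcc_frontal, pcc_per_plane(pair, "frontal"), tolerance = 0.01)
  expect_equal(r$pcc_sagittal, pcc_per_plane(pair, "sagittal"), tolerance = 0.01)
})

test_that("default cohort sampling matches the target Cobb distribution", {
  co <- generate_cohort(30, seed = 123)
  meds <- vapply(co, function(p) p$truth$cobb_frontal$primary, numeric(1))
  expect_gt(median(meds), 25)
  expect_lt(median(meds), 33)
  expect_gt(max(meds), 35)   # the range reaches severe curves
  expect_lt(min(meds), 20)   # ... and mild ones
  # n = 1 produces a single phantom with the sampled spec
  one <- generate_cohort(1, seed = 9)
  expect_length(one, 1)
  expect_s3_class(one[[1]], "phantom")
})

test_that("registration error scales linearly with marker pick noise", {
  sigmas <- c(0.5, 1, 2, 4)
  meds <- vapply(sigmas, function(s) {
    reps <- vapply(1:100, function(i) {
      ph <- generate_phantom(phantom_spec(seed = 1000 + i,
                                          marker_noise_sd_mm = s,
                                          surface_spacing_mm = 60))
      fit <- fit_rigid(ph$scan$markers, ph$truth$markers_eos)
      marker_rmse(fit, ph$scan$markers, ph$truth$markers_eos)$rmse
    }, numeric(1))
    median(reps)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  fit <- lm(meds ~ sigmas)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_lt(abs(coef(fit)[1]), 0.25 * meds[2])   # near-proportional
})
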