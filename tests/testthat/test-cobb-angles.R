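# Inflection detection, local-regression tangents, and Cobb angles.

test_that("find_inflections returns endpoints only for straight curves", {
  yy <- seq(0, 450, length.out = 40)
  cv <- smooth_curve(cbind(0.2 * yy, yy, 0 * yy), "auto", 100)
  infl <- find_inflections(cv, "frontal")
  expect_length(infl$interior, 0)
  expect_equal(infl$anchors, c(0, 450))
})

test_that("find_inflections locates the sine midpoint inflection to sub-mm accuracy", {
  cv <- sine_curve(10, 200)
  infl <- find_inflections(cv, "frontal")
  expect_length(infl$interior, 1)
  expect_lt(abs(infl$interior - 100), 0.5)
})

test_that("a double sagittal curve has exactly one interior inflection at the junction", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  cv <- smooth_curve(ph$truth$isl, "auto", 100)
  infl <- find_inflections(cv, "sagittal")
  expect_length(infl$interior, 1)
  expect_lt(abs(infl$interior - ph$truth$sagittal_junction_y), 2)
})

test_that("local linear regression is exact on straight lines and tracks sine tangents", {
  yy <- seq(0, 300, length.out = 40)
  straight <- smooth_curve(cbind(0.5 * yy + 3, yy, 0 * yy), "auto", 100)
  for (w in c(10, 30, 80))
    expect_equal(local_tangent(straight, "frontal", 150, w), 0.5,
                 tolerance = 1e-8)
  cv <- sine_curve(10, 200)
  s_true <- -10 * 2 * pi / 200          # tangent at the mid inflection
  expect_lt(abs(local_tangent(cv, "frontal", 100, 20) - s_true),
            0.02 * abs(s_true))
  # symmetric window at an extremum: slope ~ 0
  expect_lt(abs(local_tangent(cv, "frontal", 50, 20)), 5e-3)
  expect_error(local_tangent(cv, "frontal", 300, 20), "outside")
  expect_warning(local_tangent(cv, "frontal", 100, 1000), "global")
})

test_that("frontal Cobb matches the closed-form sine value and is monotone in amplitude", {
  yy <- seq(0, 450, length.out = 40)
  flat <- smooth_curve(cbind(0 * yy + 2, yy, 0 * yy), "auto", 100)
  expect_lt(cobb_frontal(flat)$primary_angle, 0.1)
  angles <- vapply(c(2, 5, 10, 20), function(A) {
    cf <- cobb_frontal(sine_curve(A, 200))
    truth <- 2 * atan(2 * pi * A / 200) * 180 / pi
    expect_lt(abs(cf$primary_angle - truth), 1)
    cf$primary_angle
  }, numeric(1))
  expect_true(all(diff(angles) > 0))
  # decreasing in wavelength span
  lengths <- vapply(c(200, 300, 400), function(L)
    cobb_frontal(sine_curve(10, L))$primary_angle, numeric(1))
  expect_true(all(diff(lengths) < 0))
})

test_that("sagittal Cobb recovers phantom angles, and mirroring swaps the labels", {
  ph <- generate_phantom(phantom_spec(kyphosis_angle_deg = 45,
                                     lordosis_angle_deg = 32, seed = 4))
  cv <- smooth_curve(ph$truth$isl, "auto", 100)
  sag <- cobb_sagittal(cv)
  expect_lt(abs(sag$kyphotic$angle_deg - 45), 1)
  expect_lt(abs(sag$lordotic$angle_deg - 32), 1)
  expect_lt(sag$lordotic$upper_y, sag$kyphotic$lower_y + 1e-6)
  # mirrored curve: labels swap, angles unchanged
  mirrored <- ph$truth$isl
  mirrored[, 3] <- -mirrored[, 3]
  sag_m <- cobb_sagittal(smooth_curve(mirrored, "auto", 100))
  expect_equal(sag_m$kyphotic$angle_deg, sag$lordotic$angle_deg, tolerance = 1e-6)
  expect_equal(sag_m$lordotic$angle_deg, sag$kyphotic$angle_deg, tolerance = 1e-6)
  # straight sagittal profile: single-curve error
  yy <- seq(0, 450, length.out = 40)
  straight <- smooth_curve(cbind(sin(yy / 80), yy, 0 * yy), "auto", 100)
  expect_error(cobb_sagittal(straight), "single-curve")
})

test_that("regression-based Cobb agrees with the dense numerical-differentiation oracle", {
  for (A in c(5, 15)) for (L in c(250, 400)) {
    cv <- sine_curve(A, L)
    oracle <- cobb_oracle_dense(function(y) eval_curve(cv, y, "frontal"), 0, L)
    expect_lt(abs(cobb_frontal(cv)$primary_angle - oracle$primary), 1)
  }
  # single-arc sagittal profiles (C-curves placed in the sagittal plane)
  for (th in c(20, 40)) {
    ph <- generate_phantom(phantom_spec(frontal_mode = "arc",
                                        frontal_arc_angle_deg = th,
                                        kyphosis_angle_deg = 0,
                                        lordosis_angle_deg = 0, seed = 1))
    ys <- seq(0, 450, length.out = 80)
    arc <- cbind(0 * ys, ys, ph$truth$funs$isl_x(ys))  # arc as z(y)
    cv <- smooth_curve(arc, "auto", 100)
    oracle <- cobb_oracle_dense(function(y) eval_curve(cv, y, "sagittal"), 0, 450)
    segs <- cobb_segments(cv, "sagittal")
    expect_identical(nrow(segs), 1L)
    expect_lt(abs(segs$angle_deg - oracle$primary), 1)
  }
})

test_that("Cobb angles are invariant to in-plane translation of the curve", {
  cv <- sine_curve(10, 300)
  shifted <- cv$points
  shifted[, 1] <- shifted[, 1] + 40
  shifted[, 2] <- shifted[, 2] - 120
  cv2 <- smooth_curve(shifted, "auto", 100)
  expect_equal(cobb_frontal(cv2)$primary_angle, cobb_frontal(cv)$primary_angle,
               tolerance = 1e-6)
})

test_that("compare_cobb summarizes paired differences and correlation", {
  a <- c(10, 20, 30, 40, 55)
  same <- compare_cobb(a, a)
  expect_equal(same$median_difference, 0)
  expect_equal(same$r, 1)
  shifted <- compare_cobb(a, a + 3)
  expect_equal(shifted$median_difference, -3)
  expect_equal(shifted$iqr_difference, 0)
  expect_equal(shifted$r, 1)
  d <- compare_cobb(c(11, 18, 34), c(10, 20, 30))
  expect_equal(d$differences, c(1, -2, 4))
  expect_equal(d$median_difference, 1)
  expect_equal(d$iqr_difference, 3)        # type-7 quantiles of (-2, 1, 4)
  expect_error(compare_cobb(1:2, 1:2), "3 pairs")
  expect_error(compare_cobb(1:3, 1:4), "equal length")
})
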