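# Spline smoothing, Procrustes superimposition and the per-plane shape PCC.

test_that("smoothing splines reproduce straight lines exactly", {
  yy <- seq(0, 450, length.out = 40)
  pts <- cbind(0.3 * yy - 10, yy, -0.1 * yy + 5)
  for (sm in list("auto", 0.8)) {
    cv <- smooth_curve(pts, sm, 100)
    expect_lt(max(abs(cv$points[, 1] - (0.3 * cv$points[, 2] - 10))), 1e-8)
    expect_lt(max(abs(cv$points[, 3] - (-0.1 * cv$points[, 2] + 5))), 1e-8)
  }
})

test_that("GCV smoothing recovers a noisy sine to within 1 mm", {
  set.seed(14)
  yy <- seq(0, 400, length.out = 60)
  x <- 10 * sin(2 * pi * yy / 400) + rnorm(60, sd = 0.5)
  cv <- smooth_curve(cbind(x, yy, 0 * yy), "auto", 200)
  expect_lt(max(abs(cv$points[, 1] - 10 * sin(2 * pi * cv$points[, 2] / 400))), 1)
})

test_that("the sampled grid honours the contract and evaluates the spline exactly", {
  yy <- seq(0, 300, length.out = 30)
  cv <- smooth_curve(cbind(sin(yy / 40), yy, cos(yy / 60)), "auto", 100)
  expect_identical(length(cv$y), 100L)
  expect_equal(range(cv$y), c(0, 300))
  expect_lt(max(abs(diff(diff(cv$y)))), 1e-9)   # equally spaced
  expect_identical(cv$points[, 1], unname(eval_curve(cv, cv$y, "frontal")))
  expect_identical(cv$points[, 3], unname(eval_curve(cv, cv$y, "sagittal")))
  expect_error(smooth_curve(cbind(0:2, 0:2, 0:2)), "at least 4")
})

test_that("Procrustes alignment undoes a rigid displacement of the moving curve", {
  cv <- sine_curve(10, 400)
  ref <- cv$points
  tf <- rigid_transform(rotation_axis_angle(c(0, 0, 1), 10 * pi / 180),
                        c(25, -40, 12))
  moved <- apply_transform(tf, ref)
  al <- procrustes_align(ref, moved)
  expect_lt(max(abs(al$points - ref)), 1e-9)
  expect_lt(al$disparity, 1e-15)
  # no scaling: centroid size of the moving set is preserved
  expect_equal(centroid_size(al$points), centroid_size(moved),
               tolerance = 1e-12)
  expect_error(procrustes_align(ref, moved[-1, ]), "same N")
})

test_that("Procrustes disparity is invariant to rigid pre-transforms of the moving curve", {
  set.seed(31)
  ref <- sine_curve(12, 420)$points
  moving <- ref + matrix(rnorm(length(ref), sd = 2), nrow(ref), 3)
  d0 <- procrustes_align(ref, moving)$disparity
  for (i in 1:5) {
    pre <- rigid_transform(random_rotation(), rnorm(3, sd = 300))
    d1 <- procrustes_align(ref, apply_transform(pre, moving))$disparity
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("pcc_per_plane implements the standardized-product correlation", {
  pair <- list(spl = cbind(c(0, 1, 2), 1:3, 0), isl = cbind(c(0, 1, 3), 1:3, 0))
  expect_equal(round(pcc_per_plane(pair, "frontal"), 4), 0.9820)
  # identical / negated sequences give exactly +/- 1
  x <- rnorm(50); m <- cbind(x, 1:50, x)
  expect_identical(pcc_per_plane(list(spl = m, isl = m), "frontal"), 1)
  expect_identical(pcc_per_plane(list(spl = m, isl = -m), "sagittal"), -1)
})

test_that("pcc_per_plane agrees with the brute-force two-pass computation", {
  set.seed(8)
  for (i in 1:100) {
    a <- rnorm(40); b <- rnorm(40)
    pair <- list(spl = cbind(a, 1:40, a), isl = cbind(b, 1:40, b))
    expect_equal(pcc_per_plane(pair, "frontal"), pcc_brute_force(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the shape PCC is invariant to positive affine rescaling and flips sign otherwise", {
  set.seed(12)
  a <- rnorm(30); b <- rnorm(30)
  base <- pcc_per_plane(list(spl = cbind(a, 1:30, 0), isl = cbind(b, 1:30, 0)),
                        "frontal")
  scaled <- pcc_per_plane(list(spl = cbind(a, 1:30, 0),
                               isl = cbind(2.5 * b + 7, 1:30, 0)), "frontal")
  flipped <- pcc_per_plane(list(spl = cbind(a, 1:30, 0),
                                isl = cbind(-0.5 * b + 1, 1:30, 0)), "frontal")
  expect_equal(scaled, base, tolerance = 1e-12)
  expect_equal(flipped, -base, tolerance = 1e-12)
})

test_that("flat sequences raise an undefined-correlation error naming the curve", {
  flat <- cbind(rep(1, 20), 1:20, rep(0, 20))
  wavy <- cbind(sin(1:20), 1:20, cos(1:20))
  expect_error(pcc_per_plane(list(spl = flat, isl = wavy), "frontal"), "SPL")
  expect_error(pcc_per_plane(list(spl = wavy, isl = flat), "sagittal"), "ISL")
})

test_that("rotation-only Procrustes matches the vegan reference implementation", {
  set.seed(19)
  ref <- sine_curve(9, 380)$points
  moving <- apply_transform(
    rigid_transform(rotation_axis_angle(c(1, 1, 0), 0.15), c(10, 20, -5)),
    ref + matrix(rnorm(length(ref), sd = 1.5), nrow(ref), 3))
  ours <- procrustes_align(ref, moving)
  # vegan centres both sets; compare after removing the reference centroid
  vg <- vegan::procrustes(scale(ref, scale = FALSE),
                          scale(moving, scale = FALSE), scale = FALSE)
  ours_centered <- scale(ours$points, scale = FALSE)
  expect_lt(max(abs(unclass(vg$Yrot) - ours_centered)), 1e-6)
})

test_that("curves are paired on the overlap of their height ranges", {
  y1 <- seq(0, 400, length.out = 50)
  y2 <- seq(100, 500, length.out = 50)
  c1 <- smooth_curve(cbind(sin(y1 / 50), y1, 0 * y1), "auto", 50)
  c2 <- smooth_curve(cbind(cos(y2 / 50), y2, 0 * y2), "auto", 50)
  pair <- pair_curves(c1, c2, 80)
  expect_equal(range(pair$y), c(100, 400))
  expect_identical(nrow(pair$spl), 80L)
  y3 <- seq(600, 700, length.out = 20)
  c3 <- smooth_curve(cbind(sin(y3), y3, 0 * y3), "auto", 20)
  expect_error(pair_curves(c1, c3), "overlap")
})
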