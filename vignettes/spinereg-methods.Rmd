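---
title: "Registering back-surface scans with biplanar radiographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering back-surface scans with biplanar radiographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinereg)
```

## The problem

Adolescent idiopathic scoliosis is monitored by repeated radiography, which
carries a cumulative radiation burden in a young population. Optical 3D
surface scanning of the back is a non-ionizing alternative, but estimates of
spinal deformity made from the back surface alone tend to underestimate the
internal deformity. Quantifying how faithfully the **spinous process line**
(SPL, the palpable line over the spinous processes on the back surface)
tracks the **internal spinal alignment** (ISL, the 3D line through the
vertebral body centroids from C7 to L5) requires bringing a 3D back-surface
scan and a pair of calibrated biplanar radiographs into a single coordinate
system. `spinereg` implements that registration and the downstream shape
analysis:

1. calibrate each radiograph view and convert pixel annotations to
   millimetres;
2. reconstruct 3D markers and the 3D ISL from the two views by orthogonal
   projection;
3. fit the rigid transform carrying the scanner frame onto the radiographic
   frame from marker correspondences (least-squares, SVD);
4. smooth both spinal lines with penalized smoothing splines, superimpose
   them by a rotation+translation-only Procrustes fit, and correlate their
   shapes per anatomical plane;
5. compute frontal, kyphotic and lordotic Cobb angles from the smoothed ISL
   by local linear regression of tangents at curvature inflection points.

A synthetic phantom generator with closed-form ground truth makes every
stage testable without clinical data.

## Coordinate conventions and biplanar geometry

The shared (radiographic) frame has y vertical and increasing cranially, x
lateral (frontal-plane deviation), and z antero-posterior, increasing
posteriorly. The frontal image plane is spanned by (x, y), the lateral by
(z, y). Pixel-to-millimetre calibration is affine, using the pixel spacing
and image position that radiographic DICOM headers carry; because image rows
count downwards while y points cranially, rows are flipped:
`y = origin_y + spacing_row * (rows - 1 - row)`.

Projections are modelled as orthogonal (parallel-beam). A slot-collimated
biplanar scanner is close to this ideal; modelling residual beam divergence
is out of scope. Under orthogonal projection, triangulation is exact and
linear: x comes from the frontal view, z from the lateral view, and the two
y observations of the same landmark are reconciled by their arithmetic mean,
with the discrepancy `|y_frontal - y_lateral|` kept as a per-marker quality
metric (flagged above 15 mm, never a hard failure). The 3D ISL is obtained
by parameterizing both drawn lines by y over the intersection of their
y-ranges and sampling x(y) and z(y) at 100 regular heights; hand-drawn lines
that locally backtrack in y are reordered (and rejected when more than 5% of
points had to move, which indicates a grossly non-monotone drawing rather
than pen jitter).

## Rigid registration

The scanner-to-radiograph transform is the closed-form least-squares rigid
fit (Kabsch): centre both marker sets, take the SVD of the cross-covariance,
and correct a reflection optimum by flipping the smallest singular
direction, guaranteeing a proper rotation. Markers are weighted uniformly.
At least 3 non-collinear correspondences are required (collinearity test:
smallest singular value of the centred source below 1e-6 of the largest).

By default the pipeline registers on **all** markers present in both
modalities (nine in the phantom protocol). The four-marker subset
(C7, L5, and the two posterior superior iliac spines) used when marker picks
are made manually is available through `pipeline_config(marker_subset =
c("C7", "L5", "PSIS_L", "PSIS_R"))`. The reason for the all-marker default
is error propagation: rotation about the vertical axis is constrained only
by the markers' lever arms in the transverse plane, roughly
`var(rotation) ~ sigma^2 / sum(r_i^2)` for pick noise sigma and transverse
distances r from the marker centroid. With four markers those lever arms are
the two PSIS offsets (~45 mm), and 2 mm pick noise alone produces about
1.4 degrees of vertical-axis rotation error; the five additional
scapular/flank markers triple the constraint. An automated pipeline pays no
extra cost for using them.

Registration quality is summarized as the RMSE of the per-marker residual
magnitudes and their SD, the standard discrepancy metrics for marker-based
registration.

## Curve model and shape correlation

Each 3D spinal line is modelled as two independent penalized smoothing
splines x(y) and z(y) (`stats::smooth.spline`), with the penalty selected by
generalized cross-validation by default (`smoothing = "auto"`); a numeric
`spar` can be fixed instead when reproducibility across cohorts of very
different noise levels matters more than per-curve adaptivity. Straight
lines lie in the null space of the roughness penalty and are reproduced
exactly at any penalty. Both curves are resampled at 100 regular heights
over their own ranges and then paired on a common grid over the overlap of
their y-ranges (the SPL spans skin landmarks, the ISL vertebral landmarks,
so the ranges differ).

The ISL is then superimposed on the SPL by a Procrustes fit restricted to
rotation and translation — the scale factor is fixed at 1, so the centroid
size of the moving curve is untouched. This makes the subsequent shape
comparison invariant to global posture differences (a rigid displacement of
either curve changes neither the alignment residual nor the correlation).
The rotation is full 3D; per-plane coordinates are extracted after
alignment.

Shape agreement per anatomical plane is the Pearson correlation of the
paired coordinate sequences (frontal plane: x, sagittal plane: z), each
standardized by its own mean and its own (N−1)-normalized standard
deviation:

$$
\mathrm{PCC}(\mathrm{SPL},\mathrm{ISL}) \;=\; \frac{1}{N-1}\sum_{i=1}^{N}
\left(\frac{\mathrm{SPL}_i-\mu_{\mathrm{SPL}}}{\sigma_{\mathrm{SPL}}}\right)
\left(\frac{\mathrm{ISL}_i-\mu_{\mathrm{ISL}}}{\sigma_{\mathrm{ISL}}}\right).
$$

The implementation computes the algebraically identical ratio of centred
sums `S_xy / sqrt(S_xx * S_yy)`, which returns exactly 1 and −1 for
identical and negated sequences. The correlation is computed on the raw
coordinate sequences after alignment, not on derivatives or deviations from
a fitted axis; this is the natural reading of the definition above, and the
alternative (correlating lateral deviations from an axis) is deliberately
not implemented. A flat sequence has no defined shape correlation, so
`pcc_per_plane()` errors on zero variance, naming the flat curve; the
pipeline layer adds one convention for degenerate spines: if *both* curves
are flat in a plane (e.g. a perfectly straight synthetic spine) their
correlation is reported as 1, and if only one is flat, as `NA` with a note.

## Cobb angles

Cobb angles are computed from the smoothed ISL. Curve segments are delimited
by the inflection points of the plane coordinate — where the second
derivative of the spline changes sign — with the curve endpoints as boundary
anchors; a single C-shaped curve has its most tilted tangents at the curve
ends, so anchoring at the endpoints lets both C- and S-curves yield angles.
Inflections are found by a sign scan on a dense grid and refined by
bisection; second derivatives below 1e-6 of the curve's maximum curvature
count as zero (so a numerically-straight spline yields no spurious
crossings), inflections within one minimum segment length (default 20 mm,
roughly a vertebral height) of an endpoint are dropped, and interior
inflection pairs closer than that length are removed pairwise, which
preserves the convexity alternation of the remaining segments.

The tangent at each anchor is the OLS slope of the spline over a window
centred at the anchor (clipped at the curve ends), evaluated at 25 dense
points; the segment's Cobb angle is
`|atan(s_upper) - atan(s_lower)|` in degrees, unsigned, as clinically
reported. The frontal measurement returns every segment plus the primary
curve (largest angle). The sagittal measurement expects one interior
inflection separating a posteriorly convex (kyphotic) from an anteriorly
convex (lordotic) segment; convexity is read from the sign of z''
(z increases posteriorly, so kyphotic segments have z'' < 0), which makes a
mirrored curve swap labels while keeping both angles. A monotone-convexity
sagittal profile raises a single-curve error (the pipeline maps the
straight-profile case, angle below 1 degree, to kyphotic = lordotic = 0).

### Choice of the regression window

The window is the one genuinely free numerical parameter. A local linear
fit estimates the tangent at the *centre of its window*: at an interior
inflection the window is symmetric and the estimate is nearly unbiased, but
at a curve endpoint the window is one-sided, so the estimate is really the
tangent about half a window inside the curve — a tilt error of roughly
(curvature x window/2) per bounded end. On strongly curved spines
(amplitude/length ratios up to 0.1, end tilt rates up to ~0.15 deg/mm) a
30 mm window accumulates 1.5–2 degrees of systematic underestimation, while
very small windows start tracking the residual ripple of the fitted spline
instead of the anatomy. A sweep over the phantom families (sine S-curves
with amplitude 2–20 mm over 200–400 mm spans, single arcs of 15–60 degrees,
double sagittal curves of 50/35 degrees) puts the worst-case error at about
2.6/1.4/0.5/0.6 degrees for 8/10/12/15 mm windows on the double sagittal
family and 0.9/0.4 degrees at 12 mm for the arc and sine families — 12 mm
(about half a vertebral height) is the only setting keeping every family
below 1 degree and is the default; it is configurable per study.

Because the ISL ends at the inferior endplate of L5 rather than the superior
endplate of S1, the lordotic angle is measured over a slightly shorter
segment than an S1-referenced clinical reading and is systematically lower;
no S1 extrapolation is attempted — this is an intrinsic limitation of the
drawn-line protocol, not of the angle computation.

Paired comparison against reference readings (`compare_cobb()`) reports the
median and IQR of the pairwise differences and the Pearson correlation with
a Fisher-z 95% confidence interval (the conventional choice; the interval
method is an assumption, not a contract). Quantiles throughout the package
are type-7 (linear interpolation), stated explicitly because different
conventions move small-sample IQRs noticeably.

## The phantom generator

`phantom_spec()`/`generate_phantom()` build a synthetic patient with exact
ground truth:

* **Frontal curve** — a sine `x(y) = A sin(2*pi*y/lambda)` (scoliotic
  S-curve; the default wavelength equals the C7–L5 span, so the spine holds
  one full S with its inflection mid-span), or a single circular arc
  (C-curve) whose Cobb angle equals the subtended arc angle exactly.
* **Sagittal curve** — a C²-smooth double curve whose tangent slope follows
  a raised cosine between prescribed values at L5, the thoracolumbar
  junction (40% of the span), and C7. The curvature vanishes at both curve
  ends and crosses zero transversally only at the junction, and the angles
  between the boundary tangents equal the requested kyphotic and lordotic
  Cobb angles in closed form. (Joined circular arcs were considered and
  rejected: their curvature jump at the junction and non-zero end curvature
  interact with the natural boundary conditions of smoothing splines and
  contaminate recovered tangents by 2–3 degrees — an artifact of the
  phantom, not of the measurement.)
* **SPL** — the ISL with frontal amplitude damped by a factor (default
  0.55), a smooth transverse skin shift (default 3 mm of half-sine), and a
  posterior depth offset (default 35 mm). The damping plus shift make the
  frontal shapes strongly but not perfectly correlated, qualitatively like
  real skin-vs-spine behaviour; the sagittal shape is preserved, so
  sagittal correlations are near 1.
* **Markers** — nine skin markers: C7, L5, the PSIS pair below L5, and five
  auxiliary (mid-thoracic, two scapular, two flank) markers with realistic
  transverse lever arms.
* **Views and annotations** — two calibrated views (0.5 mm pixels) and
  exact pixel annotations (sub-pixel picks; the drawn ISL is stored
  cranial-to-caudal as it would be drawn).
* **Scan bundle** — markers, SPL and a surface patch (a 120 mm-wide sheet
  around the SPL with mild transverse curvature, ~5 points/cm²) expressed
  in a scanner frame displaced by a known rigid postural transform, with
  seeded Gaussian noise added to the scanner-side marker picks
  (`marker_noise_sd_mm`, per coordinate) and the surface
  (`surface_noise_sd_mm`). Radiograph picks are exact: the dominant
  real-world error — the patient re-posing between modalities and the
  operator picking marker centres on a scanned surface — lives on the
  scanner side.

`generate_cohort()` samples phantom parameters emulating a scoliosis study
population: target frontal Cobb angles `9 + 45*Beta(1.2, 1.5)` degrees
(median near 29, range 9–54), kyphosis 25–55 and lordosis 25–50 degrees,
spans 400–480 mm, postural offsets of 5–20 degrees about a random axis with
translations up to ±500 mm, and 2 mm marker pick noise. All randomness
derives from the cohort seed; identical seeds give byte-identical folders.

What the phantoms do *not* emulate: anatomically realistic back surfaces,
non-rigid posture change between modalities, radiographic image content
(annotations arrive as coordinates, as in the real workflow), or
operator-dependent drawing error. Passing phantom tests therefore validates
the geometry, registration, smoothing, correlation and angle machinery —
not reading accuracy on clinical images.

## Numerical choices and degenerate inputs

* Zero-variance sequences: error at the module surface, documented
  conventions at the pipeline surface (see above).
* Collinear marker sets: rejected before the SVD (threshold 1e-6 relative).
* Straight curves: splines reproduce them exactly; inflection search
  returns endpoints only; frontal Cobb is ~0.
* y-monotonicity of drawn lines: reorder, average duplicate heights, reject
  above 5% disorder.
* Quantiles: type 7 everywhere.
* Determinism: every stochastic step draws from an explicit seed; result
  files embed the input annotations' timestamps, never the wall clock, so
  re-running a batch on unchanged inputs reproduces identical files
  (stage timings go to the stderr log).

## Problem sizes used in the validation suite

The test-suite and acceptance computations use 1000-point round-trip
clouds, 500 random transform refits, 100 random sequence pairs for the
correlation equivalence, a 30-patient noisy cohort processed end-to-end,
and 100 registration replicates per noise level across pick-noise SDs of
0.5–4 mm; these sizes give stable medians while keeping a full run in the
tens of seconds.

## Known limitations

* The orthogonal-projection model ignores residual beam divergence.
* Marker-based registration only; no surface ICP refinement, no non-rigid
  registration.
* Linear (Pearson) shape correlation only; rank or distance correlations
  and statistical shape models are out of scope.
* The lordotic angle is L5-referenced (see above).
* No vertebra detection or level labelling: anatomical levels are implicit
  in the drawn lines.
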