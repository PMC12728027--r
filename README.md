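# spinereg

Registration of 3D back-surface scans with biplanar radiographs, and the
shape analysis that registration enables, for research on scoliosis.

## The problem

Scoliosis is clinically assessed from radiographs — at the cost of repeated
radiation exposure in adolescents. Optical 3D scanning of the back is
non-ionizing, but deformity estimates made from the back surface alone tend
to underestimate the internal deformity. Understanding *how* the back
surface tracks the spine requires bringing a 3D surface scan and a pair of
calibrated biplanar radiographs (frontal + lateral) into one coordinate
system, then comparing the **spinous process line** (SPL, drawn on the
scanned back surface) with the **internal spinal alignment** (ISL, the line
through vertebral body centroids drawn on both radiographs).

`spinereg` implements that pipeline:

1. **Biplanar geometry** — affine pixel-to-millimetre calibration per view
   (DICOM-derived pixel spacing / image position via JSON sidecars);
   reconstruction of 3D markers and the 3D ISL from the two views by
   orthogonal projection. A marker observed at heights `y_f`, `y_l` in the
   two views is triangulated as `(x_f, (y_f + y_l)/2, z_l)` with
   `|y_f − y_l|` kept as a quality metric.
2. **Rigid registration** — closed-form least-squares fit (SVD/Kabsch) of
   the proper rigid transform mapping scanner-frame markers onto the
   triangulated radiographic markers, applied to the scan bundle; marker
   RMSE and residual SD as quality metrics.
3. **Curve analysis** — penalized smoothing splines `x(y)`, `z(y)` per
   line (GCV-selected penalty), resampling on a common height grid,
   rotation+translation-only Procrustes superimposition of the ISL on the
   SPL (no scaling), and the per-plane Pearson shape correlation

   PCC(SPL, ISL) = 1/(N−1) · Σᵢ ((SPLᵢ − μ_SPL)/σ_SPL) ((ISLᵢ − μ_ISL)/σ_ISL)

   computed separately for the frontal (x) and sagittal (z) planes.
4. **Cobb angles** — frontal, kyphotic and lordotic angles from the
   smoothed ISL: segments delimited by curvature inflection points (curve
   endpoints as boundary anchors), boundary tangents by local linear
   regression (12 mm window), angle = |atan s₁ − atan s₂| in degrees;
   paired comparison against reference readings with median/IQR differences
   and Pearson r with Fisher-z CI.
5. **Phantom generator** — synthetic patients (parametric scoliotic
   ISL/SPL, nine skin markers, biplanar annotations, surface point cloud,
   known rigid postural offset, seeded noise) with closed-form ground-truth
   Cobb angles, so every stage is validated without clinical data.
6. **Batch processing & CLI** — per-patient folders in, per-patient JSON
   results and cohort median/IQR summaries out; a thin command-line wrapper
   (`inst/cli/spinereg.R`) with `phantom`, `process`, `batch`, `summarize`
   and `compare-cobb` subcommands.

## Worked example

```r
library(spinereg)

# a synthetic patient: 12 mm frontal S-curve, 45/38 deg sagittal targets,
# a 10 deg postural offset between scanner and radiograph frames,
# 2 mm marker pick noise
spec <- phantom_spec(frontal_amplitude_mm = 12, kyphosis_angle_deg = 45,
                     lordosis_angle_deg = 38, marker_noise_sd_mm = 2,
                     postural_transform = rigid_transform(
                       rotation_axis_angle(c(0, 1, 0), 10 * pi / 180),
                       c(250, -120, 80)),
                     seed = 11)
phantom <- generate_phantom(spec)
phantom
#> <phantom> seed 11: frontal Cobb 19.0 deg, kyphosis 45, lordosis 38, 2727 surface pts

dir <- file.path(tempdir(), "patient_demo")
write_phantom(phantom, dir)     # radiograph sidecars, annotations, scan bundle
result <- process_patient(dir)  # triangulate -> register -> correlate -> Cobb
result
#> <patient_result> patient_demo: RMSE 2.41 mm, PCC 0.995/1.000 (frontal/sagittal),
#>   Cobb 19.0/44.9/37.8 deg (frontal/kyphotic/lordotic)
```

The registration RMSE (2.41 mm) reflects the simulated 2 mm marker pick
noise; the recovered postural rotation is 0.29 degrees from the simulated
one; the frontal Cobb angle (19.0 deg) matches the phantom's closed-form
truth, and the kyphotic/lordotic angles (44.9/37.8) recover the 45/38
targets. The shape correlations say the skin line tracks the spine almost
perfectly in the sagittal plane (1.000) and strongly in the frontal plane
(0.995 — the phantom dampens the frontal amplitude at the skin).

A cohort is one call each way:

```r
cohort <- generate_cohort(10, seed = 1)
root <- file.path(tempdir(), "cohort_demo")
write_cohort(cohort, root)
summarize_cohort(batch_process(root))
#> <cohort_summary> 10 processed, 0 failed
#>   marker_rmse    median    3.001  IQR    0.502  (n = 10)
#>   residual_sd    median    1.154  IQR    0.179  (n = 10)
#>   pcc_frontal    median    0.988  IQR    0.008  (n = 10)
#>   pcc_sagittal   median    0.998  IQR    0.002  (n = 10)
#>   cobb_frontal   median   31.279  IQR   25.970  (n = 10)
#>   cobb_kyphotic  median   36.444  IQR   10.538  (n = 10)
#>   cobb_lordotic  median   36.901  IQR   16.764  (n = 10)
```

Or from a shell:

```sh
Rscript inst/cli/spinereg.R phantom cohort_dir --n 10 --seed 1
Rscript inst/cli/spinereg.R batch cohort_dir --out summary.json
```

See `vignettes/spinereg-methods.Rmd` for the models, parameter choices and
limitations.

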