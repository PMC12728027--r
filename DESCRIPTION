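Package: spinereg
Title: Registration of 3D Back-Surface Scans with Biplanar Radiographs and
    Spinal Curve Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Registers 3D back-surface scans with biplanar (frontal/lateral)
    radiographs of patients with scoliosis via marker triangulation and a
    least-squares rigid (Kabsch/SVD) fit, reconstructs the 3D internal spinal
    line from biplanar annotations, smooths spinal lines with penalized
    smoothing splines, quantifies the per-plane Pearson correlation between
    the spinous process line and the internal spinal alignment after a
    rotation-and-translation-only Procrustes superimposition, and computes
    frontal, kyphotic and lordotic Cobb angles by local linear regression of
    curve tangents at curvature inflection points. Includes a synthetic
    phantom generator with closed-form ground truth for validating every
    pipeline stage, batch processing of patient folders, and cohort summary
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
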