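Package: doseAccum
Title: Automated Daily Dose Accumulation for MR-Guided Online Adaptive
    Radiotherapy
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for fraction-by-fraction dose accumulation quality
    assurance in MR-guided online adaptive radiotherapy. Provides a synthetic
    pelvis phantom with ground-truth deformation fields, rigid and hybrid
    (contour + intensity) deformable image registration restricted to a
    target-focused region, warping of daily delivered fraction doses back to
    the planning frame, a progressive composite dose that replaces the
    planned dose fraction by fraction, dose-volume-histogram metrics and
    institutional constraint-template evaluation with a replanning trigger,
    and validation metrics (Dice, Jaccard, Hausdorff distances, 3D gamma
    analysis, two-sample t-tests). Volumes are exchanged as NIfTI; DICOM RT
    Dose and RT Structure Set readers are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
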