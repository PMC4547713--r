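Package: longmdt
Title: Longitudinal MRI Morphometry with Subject-Specific Templates and
    Spatio-Temporal Regularization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for longitudinal structural MRI analysis: cross-sectional
    preprocessing (patch-based denoising, intensity non-uniformity correction,
    percentile-anchored intensity normalization, hierarchical linear
    registration), iterative subject-specific linear and non-linear minimum
    deformation templates, spatio-temporal regularization of the 4D
    deformation trajectory, template-based longitudinal bias-field correction,
    Jacobian-determinant structure volumetry, and linear mixed-effects power
    analysis with Diggle sample-size estimation and parametric bootstrap.
    Includes a ground-truth 4D phantom generator emulating scan-rescan and
    two-group longitudinal cohort designs so every pipeline stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    lme4,
    minqa,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
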