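Package: nirscr
Title: Short-Channel Regression and Test-Retest Reproducibility for fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for functional near-infrared spectroscopy (fNIRS) motor-task
    studies: synthetic study generation with known ground truth, conversion of
    raw optical intensities to hemoglobin concentration changes via the modified
    Beer-Lambert law, spline motion correction and zero-phase FIR band-pass
    filtering, multichannel non-negative short-channel regression inside a GLM
    with canonical hemodynamic response and temporal/dispersion derivatives,
    baseline-derived activation thresholds, signal-quality and Mayer-wave
    metrics, test-retest reproducibility statistics (Pearson correlation,
    two-way random absolute-agreement intraclass correlations with confidence
    intervals, scaled mean absolute error), and a pseudo-online left-vs-right
    hand-grasping classifier with causal filtering, adaptive non-negative
    sample-wise regression and L1-regularized feature selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    jsonlite
Suggests:
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
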