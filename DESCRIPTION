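Package: boldcaps
Title: Co-Activation Pattern Analysis of Resting-State BOLD fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Seed-based co-activation pattern (CAP) analysis of 4D BOLD
    time series. Reduces a resting-state session to a spatio-temporal
    point process by thresholding a seed (e.g. posterior cingulate)
    signal, clusters the supra-threshold whole-brain frames with k-means
    (optionally around fixed reference centroids so cluster indices are
    comparable across experimental conditions), and compares the
    resulting CAPs across conditions with within-subject linear
    contrasts under Benjamini-Hochberg false-discovery-rate control.
    Includes the standard temporal and spatial preprocessing chain
    (polynomial detrending, zero-phase Butterworth bandpass, nuisance
    regression, Gaussian smoothing, voxelwise standardization),
    framewise-displacement and DVARS motion quality control, and a
    synthetic multi-subject cohort generator with planted co-activation
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    signal,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
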