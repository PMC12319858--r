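Package: tcmap
Title: Temporal Coherence Mapping for Time Series and Functional Neuroimaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies long-range temporal coherence, anti-coherence, and
    their balance in one-dimensional time series via correlations between
    temporal-embedding vectors (the TCM matrix), and applies the method
    voxelwise to 4D functional MRI volumes to produce six parametric maps:
    mean positive correlation (TC), mean negative-correlation magnitude
    (TAC), their difference (CAB1), normalized diagonal-line lengths of the
    thresholded positive and negative matrices (MLP, MLN), and their
    difference (CAB2). Includes a memory-frugal diagonal-streaming
    implementation with an explicit full-matrix reference path, synthetic
    benchmark signal generators (sinusoid, white Gaussian, 1/f noise),
    NIfTI-1 volume mapping with deterministic parallelism, test-retest
    intraclass-correlation assessment, and respiration/heart-rate extraction
    from high-frequency physiological recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    signal,
    stats,
    parallel,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
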