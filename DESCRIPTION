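Package: roipower
Title: Simulation-Based Power Analysis for Spatial Transcriptomics Region-of-Illumination Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning NanoString GeoMx-style region-of-illumination (ROI)
    experiments from spot-level spatial transcriptomics reference data. Provides a
    synthetic-data generator for Visium-like spot grids and bulk RNA-seq cohorts,
    an endpoint-discovery stage (median-of-ratios normalization, covariate-adjusted
    candidate-gene screens, gene-set summary scores, score co-localization, and
    percentile-based tissue segmentation into fibrotic-niche and hepatocyte
    compartments), spike-in calibration curves that translate bulk-tissue log2
    fold changes into compartment-level effect sizes, a GeoMx ROI simulator
    (spot aggregation by ROI diameter, patient assignment, dropout), negative
    binomial mixed models with patient random intercepts fitted by adaptive
    Gauss-Hermite quadrature with TMM effective-library-size offsets, and a power
    engine that estimates rejection rates over grids of design conditions.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    MASS,
    Matrix,
    edgeR,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
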