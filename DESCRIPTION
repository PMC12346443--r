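Package: ethomanifold
Title: Behavior Post-Processing and Neuronal-Manifold Analysis for Miniscope Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing one-photon calcium-imaging sessions of freely
    behaving mice together with video-derived behavior: composite RGB frame
    construction for behavior scoring, analytical segmentation of a circular
    arena into concentric zones, key-point evaluation with the PCK metric,
    probabilistic smoothing of behavior label streams, kinematic summaries,
    temporal-window flattening of population calcium activity into manifold
    point clouds, dimensionality reduction (t-SNE, PCA, ICA, MDS, UMAP), the
    intracluster-distance compactness metric, behavior-epoch covariance
    ellipse descriptors, shuffle-controlled group classification, and a
    synthetic-cohort generator that emulates wild-type versus transgenic
    recordings for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    signal,
    Rtsne,
    uwot,
    ica,
    EBImage,
    png,
    jsonlite,
    withr,
    MASS
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
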