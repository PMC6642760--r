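Package: MultiSenseHAR
Title: Multi-Sensor Human Activity Recognition from Biosignals and
    Silhouette Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for recognizing twelve
    elementary human activities (squatting, sitting, reaching, bending,
    stepping, each with its forward and return phase) from four
    synchronized sensing modalities: eight-channel surface
    electromyography, a 64-sensel plantar pressure insole system, a
    triaxial sternum accelerometer, and a side-view silhouette video
    camera. Provides a deterministic synthetic cohort generator,
    per-sensor feature-extraction chains (rectified and smoothed EMG
    envelopes, pressure region averages, offset-corrected acceleration,
    and Horn-Schunck optical-flow direction histograms on the moving
    silhouette contour), fixed-width window normalization, 1-nearest-
    neighbour classification under the Manhattan metric with
    leave-one-out model selection, and weighted recognition-rate and
    dispersion statistics with column-normalized confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MultiSenseHAR-package.R'
    'RcppExports.R'
    'accessors.R'
    'archetypes.R'
    'windowing.R'
    'biosignal.R'
    'classify.R'
    'evaluate.R'
    'io.R'
    'video-features.R'
    'pipeline.R'
    'video-render.R'
    'simulate.R'
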