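Package: SeqCover
Title: Sequential Binary Random-Forest Land-Cover and Ecosystem-Extent Mapping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for country-style land-cover and ecosystem
    extent mapping from multi-date optical satellite imagery. Implements
    QA-bit cloud masking and per-band per-pixel median compositing, a set of
    reflectance-based spectral indices, a two-phase pre-classification
    masking step (spectral thresholds plus ancillary spatial constraints),
    sequential binary random-forest classification in which classes are
    mapped one at a time and removed from subsequent iterations, dual-season
    SAR HH-amplitude mapping of permanent and seasonally flooded forests
    constrained by a digital elevation model, and stratified accuracy
    assessment (error matrices, overall, user's, producer's and binary-class
    accuracy with confidence intervals) together with area summaries. A
    synthetic-scene generator produces multispectral scene collections,
    ancillary vector layers, SAR season pairs and ground-truth labels with
    the statistical structure the classifier assumes, so the whole pipeline
    is testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, jsonlite, yaml, randomForest
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RasterGrid-methods.R'
    'spatial-utils.R'
    'legend.R'
    'config.R'
    'synthetic.R'
    'compositing.R'
    'indices.R'
    'masking.R'
    'classifier.R'
    'sar.R'
    'accuracy.R'
    'io.R'
    'pipeline.R'
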