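Package: adcascade
Title: Cascade Gait and EEG Classification for Three-Way Alzheimer's Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage ("cascade") classification of subjects into cognitively
    healthy controls (HC), mild cognitive impairment (MCI) and Alzheimer's
    disease (AD). Stage one classifies Kinect V2 skeleton gait clips with an
    attention-based spatial-temporal graph convolutional network (AST-GCN);
    stage two classifies raw resting-state EEG epochs of subjects flagged as
    patients with a spatial-temporal convolutional network (ST-CNN); subject
    labels are obtained by majority voting over clips and epochs. Includes the
    full preprocessing pipelines (skeleton rotation, centering, windowing and
    key-point selection; EEG common-average re-referencing, anti-aliased
    downsampling and eyes-open/eyes-closed epoching), a synthetic cohort
    generator with configurable group effect sizes so every stage is testable
    without clinical data, training and evaluation harnesses, and readers and
    writers for skeleton CSV/JSON-lines and EDF recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'nn-core.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'adcascade-package.R'
    'skeleton-graph.R'
    'astgcn.R'
    'stcnn.R'
    'cascade.R'
    'eeg-pipeline.R'
    'gait-pipeline.R'
    'synthetic.R'
    'experiment.R'
    'io-edf.R'
    'io-skeleton.R'
    'io-config.R'
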