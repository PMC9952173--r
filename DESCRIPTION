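Package: tstn
Title: Spatial-Temporal Transformer Decoding of Motor-Imagery EEG with
    Continual Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for three-class motor-imagery brain-computer interfaces:
    a seeded synthetic EEG session generator with a controllable mu-rhythm
    event-related desynchronization (ERD) effect, preprocessing (Butterworth
    band-pass, decimation, epoch assembly), a one-versus-rest common spatial
    pattern (CSP) filter bank, a transformer-based spatial-temporal network
    (TSTN) classifier with spatial self-attention, convolutional patch
    embedding and temporal multi-head attention, a continual-learning
    training cascade that refines the classifier across sessions using only
    correctly classified trials, confusion-matrix metrics, and ERD/ERS
    relative-power maps. Includes EDF and epoch-archive input/output and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'tstn-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'csp.R'
    'erd.R'
    'io.R'
    'metrics.R'
    'model.R'
    'preprocess.R'
    'synth.R'
    'train.R'
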