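Package: cryosift
Title: Quality Scoring and Iterative Curation of Cryo-EM 2D Class Averages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Assesses the quality of single-particle cryo-EM 2D class averages
    with a convolutional neural network regressor that fuses the class image
    with per-class metadata (pixel size, FRC resolution estimate, class
    distribution and three mass-deviation features), and drives an iterative
    classify-score-route policy that banks good particles, discards junk and
    emits nested particle batches at fixed score cutoffs. Includes MRC2014 and
    STAR file handling, pixel-intensity mass estimation with calibration on
    known-mass standards, a synthetic class-average generator for desk-scale
    training and validation, and a command-line interface.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
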