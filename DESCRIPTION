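Package: scanscreen
Title: Velocity-Encoded Scanpath Imaging and Classification for
    Eye-Tracking-Based Autism Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms raw screen-based eye-tracking recordings into
    velocity-encoded grayscale scanpath images, classifies them with a
    small convolutional neural network under image-wise and
    participant-wise cross-validation, and quantifies the relationship
    between gaze velocity and autism severity (CARS) with the maximal
    information coefficient. Includes a synthetic fixation-saccade gaze
    simulator so the full pipeline is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
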