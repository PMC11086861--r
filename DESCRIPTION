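Package: spinemark
Title: Lumbar Spine MRI Annotation with Disc Height Measurement and
    Pfirrmann Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates and names each intervertebral disc on a mid-sagittal
    T2-weighted lumbar spine MRI slice given a six-region segmentation label
    image, measures disc heights geometrically in millimetres, and predicts
    Pfirrmann degeneration grades by combining a disc-height rule with
    machine-learning classification on self-similar greyscale correlogram
    features extracted from the disc nucleus. Includes label-map validation
    and post-processing, morphological-thinning centerline extraction with
    A-star path ordering, segmentation quality metrics, and a seeded synthetic
    phantom generator so the complete pipeline can be exercised and tested
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    Matrix,
    png,
    jsonlite,
    MASS,
    class,
    e1071,
    nnet,
    rpart,
    ranger,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
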