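Package: koagrader
Title: Hybrid Radiographic Knee-Osteoarthritis Grading
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kellgren-Lawrence grading of knee radiographs with a hybrid
    feature pipeline: region-of-interest localization by sliding-window
    HOG template matching under a mean-absolute-difference score, optional
    region-based active-contour refinement, feature extraction by histogram
    of oriented gradients, local binary patterns and a small convolutional
    network, feature-level fusion, and multi-class classification by support
    vector machine, k-nearest neighbours or random forest. Includes a seeded
    synthetic radiograph generator with grade-controlled joint-space width
    for fully reproducible benchmarking, and an evaluation module with
    binary and five-class confusion matrices and percentage-split
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    png,
    randomForest,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
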