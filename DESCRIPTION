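Package: tenduseg
Title: Tendon and Synovial Sheath Segmentation in Finger Ultrasound with a
    Deeply Supervised Dilated FC-DenseNet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of the flexor tendon and synovial sheath in
    transverse finger ultrasound images with a deeply supervised dilated
    fully convolutional DenseNet (D2FC-DN). Provides the network builder
    with dilated dense blocks and three auxiliary supervision heads, a
    CPU training loop (RMSProp, polynomial learning-rate decay, weighted
    soft-Dice deep-supervision loss), offline and online data
    augmentation, a seeded synthetic speckle-phantom generator with a
    clear/fuzzy image classifier, and the full evaluation suite: Dice
    similarity coefficient, mean absolute contour distance, Hausdorff
    distance, the Yasnoff measure, and a convex-hull Hausdorff distance
    for contour smoothness, with artifact filtering and batch CSV
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
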