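Package: mdshape
Title: Moment-Distance Spectral Shape Indices and Object-Based Random
    Forest Classification of Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the moment-distance family of spectral curve shape
    metrics (MD from the left and right pivots, their difference MDI,
    normalized difference MDIN, and the pivot ratios MDRLR and MDRRL) on
    single reflectance curves and whole hyperspectral cubes, and embeds
    them in a complete object-based classification workflow: broadband
    and narrow-band vegetation indices, gray-level co-occurrence texture
    features on principal-component score images, deterministic
    region-merging segmentation, stratified train/test splitting, random
    forest classification with permutation variable importance, and
    accuracy assessment (overall, producer's and user's accuracy, kappa,
    and McNemar's paired Z test). Includes a seeded synthetic scene
    generator that builds shape-confusable class pairs with matched
    broadband means but distinct fine spectral structure, an ENVI
    raster reader/writer, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    randomForest,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
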