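Package: freshwt
Title: Machine-Vision Fresh Weight Estimation for Top-View Rosette Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for non-destructive fresh weight estimation
    of rosette crops (e.g. butterhead lettuce) from top-view RGB images, as
    used in plant-factory phenotyping. Generates synthetic labelled imagery
    with a known allometric weight law, segments plants with a
    watershed-seeded GrabCut, extracts contour morphometrics (area,
    perimeter, fitted-ellipse axes), and fits and compares a full grid of
    linear/polynomial regressors over all feature subsets together with
    three small neural regressors (a feature MLP, a flattened-image MLP and
    a convolutional network) trained by Adam on mean-squared error. Reports
    R-squared, RMSE in grams, Pearson correlation structure, kernel density
    overlays of predicted versus true weight, and per-image inference time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
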