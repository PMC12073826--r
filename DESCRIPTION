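Package: doublecrop
Title: Field-Scale Double-Cropping Detection from NDVI Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cropping intensity (single- versus double-cropping) of
    agricultural fields from irregularly sampled field-scale NDVI time
    series. Implements the standard denoising chain (daily-growth jump
    repair, negative clipping, 10-day maximum-value compositing,
    Savitzky-Golay smoothing), a rule-based NDVI-ratio cycle counter with
    start/end-of-season detection at a 0.5 threshold and a 40-day minimum
    cycle length, and trained classifiers (radial SVM, random forest, and
    k-nearest-neighbours with dynamic time warping) with crop-stratified
    train/test splitting, minority-class oversampling inside
    cross-validation folds, and stratified map-accuracy assessment
    (overall, user's and producer's accuracies with standard errors, plus
    area-proportional confusion matrices). A synthetic crop-phenology
    generator with known labels makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    ranger,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
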