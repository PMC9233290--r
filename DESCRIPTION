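Package: fundusseg
Title: Lesion-Level Detection Evaluation and ICDR Grading for Six-Field Fundus Images
Version: 0.1.0
Authors@R:
    person("Open", "Retina", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating pixel-level retinal lesion segmentations at the
    level of individual abnormalities (connected components matched by one-pixel
    overlap), for quantifying inter-annotator agreement on lesion counts with the
    intraclass correlation coefficient, for overlapping-tile full-resolution
    inference around a pluggable pixelwise predictor, and for rule-based grading
    of diabetic retinopathy on the five-level ICDR scale with quadratic weighted
    kappa and macro one-vs-rest AUC. Includes a seeded synthetic six-field
    fundus-image generator that produces paired lesion masks, a simulated second
    annotator, corrupted model outputs, and stratified train/tune/test splits, so
    the whole pipeline can be exercised end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
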