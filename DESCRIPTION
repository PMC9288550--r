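Package: facecolr
Title: Facial Colour Characteristics and Colour-Based Preference Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Extracts nineteen CIELAB facial colour characteristics (average
    and local skin colour, skin colour variation via the mean colour
    difference from the mean, and Michelson/Delta-E colour contrasts of the
    eyes, eyebrows and mouth against their surrounding skin) from
    label-mapped face images, and relates them to psychophysical preference
    ratings (attractiveness, healthiness, perceived age) through zero-order
    correlations, repeated cross-validated class-comparison regressions and
    an elastic-net predictor-importance model.  Ships a synthetic face-cohort
    generator with known ground truth so the whole pipeline is testable
    without access to calibrated face-image databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
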