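Package: carposort
Title: Morphometric Sorting and Variety Classification of Charred Grape Pips
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how charring deforms grape pips (seeds) and
    for deciding which archaeological pips are still classifiable to variety.
    Provides a calibrated synthetic pip generator (tapered ovoid with ventral
    infold grooves, anisotropic charring shrinkage and crack dropout),
    height-map scan simulation and preprocessing, automated length/width/DVI
    morphometry, pairwise ICP registration producing MSE similarity features,
    regularized linear discriminant classification with tournament
    resampling, a quadratic length-width-ratio versus charring-temperature
    calibration curve with inversion-based temperature estimates and
    accept/reject sorting, and two-way ANOVA with Tukey-Kramer compact letter
    displays for condition comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
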