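Package: rdkmix
Title: Von Mises Mixture Modeling of Feature-Continuous Motion Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for feature-continuous motion psychophysics with random dot
    kinematograms (RDKs): constrained randomized trial designs, frame-accurate
    simulation of transparent, Brownian and limited-lifetime white-noise motion
    stimuli, synthetic generation of continuous direction reports, maximum
    likelihood fitting of a five-parameter von Mises mixture model separating
    detection, report-of-opposite-direction and guessing components, nested
    model comparison with Akaike weights and model-averaged parameter
    estimates, and a permutation two-sample Cramer-von Mises test for report
    biases on the circle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
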