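Package: fuzzyair
Title: Fuzzy Inference Modelling of Air Pollution and Pediatric
    Respiratory Hospitalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Mamdani fuzzy-inference model that maps daily air-pollutant
    concentrations (PM10, NO2) and meteorology (air temperature, wind
    speed) to a predicted number of daily hospitalizations of children
    for respiratory disease, following an expert-elicited rule base
    developed for a Brazilian sugarcane-burning region.  Provides a
    generic fuzzy engine (trapezoidal and triangular membership
    functions, min/max Mamdani inference, centroid defuzzification), the
    specific four-input/sixteen-rule respiratory model, a validation
    layer (lagged Pearson correlation and ROC/AUC with Hanley-McNeil or
    DeLong confidence intervals), and a seasonal Poisson synthetic-data
    generator so the whole pipeline can be exercised without access to
    the original hospitalization and air-quality databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
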