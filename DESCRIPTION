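Package: hopalpha
Title: Agroclimatic Prediction of Alpha-Acid Content in Hop Cones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the alpha-acid content (% of cone dry matter) of hop
    (Humulus lupulus L.) cv. Aurora from two agroclimatic accumulations over
    the phenological window between second germination after spring pruning
    (F3) and technological maturity of the cones (F9): the effective
    temperature sum above a 5 degree Celsius base and the rainfall sum. The
    empirical rational-polynomial model is gated by mean July reference crop
    evapotranspiration (predictions are flagged unreliable above 4.5 mm/day),
    and its cultivar coefficients can be recalibrated from assayed seasons by
    linear least squares. Includes daily-weather CSV input, a deterministic
    synthetic-season generator, validation against laboratory assay
    tolerances (EBC 7.4 repeatability and reproducibility borders), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
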