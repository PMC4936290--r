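Package: satiecast
Title: Neural-Network Prediction of Appetite VAS Time Courses from
    Satiety-Hormone Curves
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hunger- and satiety-related Visual Analog Scale (VAS)
    time courses (desire to eat, hunger, fullness, satiety; 0-100) from
    postprandial plasma satiety-hormone curves (GLP-1, CCK, PYY). Hormone
    curves are expanded into temporal interaction products and Thomson
    multitaper power-spectral-density features and mapped to whole VAS
    curves by a log-sigmoid multilayer feed-forward network trained with
    validation-based early stopping. Companion networks impute missing
    hormone channels from any single measured hormone and extend short
    hormone series autoregressively to a prescribed length. A synthetic
    study generator with known ground truth emulates crossover
    satiety-study designs so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
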