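Package: mediumopt
Title: Surrogate-Assisted Multi-Objective Optimization of Tissue-Culture Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling and optimizing plant tissue-culture medium
    composition from factorial experiments. Fits Gaussian radial-basis-function
    (RBF) surrogates to growth responses (proliferation rate, shoot number,
    shoot length, basal callus weight) as functions of medium factors (BAP,
    IBA, phloroglucinol, sucrose), optimizes all four responses simultaneously
    with a real-coded elitist NSGA-II, selects a single recommended recipe by
    scaled ideal-point distance, and ranks factor importance by variable
    sensitivity ratios (VSE/VSR). Ships the chrysanthemum shoot-proliferation
    factorial experiment as a built-in dataset together with a calibrated
    replicate-level simulator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
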