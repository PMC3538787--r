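Package: devtiming
Title: Cross-Species Translation of Neurodevelopmental Event Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts unknown neurodevelopmental event timings (post-conceptional
    days) across mammalian species from a sparse species-by-event table. Implements
    the Finlay-Darlington offset-log dummy-variable regression with a data-estimated
    offset, a single-hidden-layer feed-forward neural network trained by
    weight-decay-penalized least squares with random restarts, leave-one-out
    cross-validation for hyperparameter selection, absolute-error threshold profiles
    decomposed into primate and non-primate contributions, and a synthetic-data
    generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tidyr,
    utils
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
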