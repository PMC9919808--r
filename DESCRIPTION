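Package: harcascade
Title: Hierarchical Cascade Classification of Activities from Chest-Worn
    Accelerometer Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising five daily activities (cough, fall, sit,
    walk, sleep) from a low-rate chest-worn tri-axial accelerometer. Implements
    per-sample feature engineering (raw accelerations, sample-to-sample deltas,
    delta magnitude, roll/pitch changes), a hierarchical classifier cascade that
    first separates normal from abnormal motion and then routes to specialised
    sub-models, a flat five-class baseline, a stratified evaluation harness
    (confusion matrices, precision/recall/F1, hold-out splits, paired k-fold
    comparison of seven classical algorithms), streaming event semantics with
    fall latching and daily cough-episode counting, and a synthetic signal
    generator for labelled accelerometer streams.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
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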