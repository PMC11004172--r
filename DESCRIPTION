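Package: everflow
Title: Deep-Learning Screening of Acute Leukemia from ALOT Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase deep-learning workflow for screening acute leukemia
    from EuroFlow acute leukemia orientation tube (ALOT) flow-cytometry data.
    Reads and writes 12-channel FCS 3.0/3.1 list-mode files; classifies single
    events into sixteen physiological and pathological cell types with the
    EverFlow one-dimensional convolutional architecture; classifies patients
    into five diagnostic groups either from rendered event-cloud density
    images or from AI-derived cellular composition features with small
    residual networks; and evaluates everything with stratified splits,
    five-fold cross-validation and one-vs-rest diagnostic metrics. A bundled
    synthetic ALOT cohort simulator makes the full pipeline testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
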