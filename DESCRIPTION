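Package: srdemg
Title: Signal Recording Duration Analysis for Myoelectric Pattern Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and evaluation pipeline for studying how the duration of
    surface electromyogram (EMG) recordings affects gesture decoding in
    pattern-recognition prosthesis control. Generates labelled multichannel
    synthetic EMG with configurable noise and fatigue-like drift, extracts
    classical time-domain feature sets (Hudgins TD4, a six-descriptor NTDF set,
    RMS) over overlapping analysis windows, trains LDA, KNN and random-forest
    decoders, and scores them under Within-SRD and Between-SRD train/test
    scenarios using classification accuracy, macro-averaged Matthews
    correlation, and Friedman rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    MASS,
    class,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
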