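Package: ssstn
Title: Subject-to-Subject Semantic Style Transfer for EEG Motor Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for feature-level subject-to-subject style transfer in
    EEG-based motor-imagery brain-computer interfaces. Epoched EEG is
    converted to Morlet continuous-wavelet-transform scalogram images,
    per-subject squeeze-and-excitation convolutional classifiers are
    pretrained, and a convolutional encoder-decoder generator maps a
    low-performing ("BCI illiterate") subject's scalograms into the feature
    space of the best-performing ("BCI expert") source subject by minimizing
    a weighted combination of a Gram-matrix/Kullback-Leibler style loss, a
    cross-classifier content loss, and a semantic cross-entropy loss. Final
    predictions combine the source and target classifiers by soft voting.
    Includes a controllable event-related desynchronization (ERD) simulator
    so the whole pipeline is testable without access to recorded EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
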