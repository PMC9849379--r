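Package: cvpac
Title: Complex-Valued Phase-Amplitude Coupling Analysis of Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes complex-valued phase-amplitude coupling (CV-PAC)
    comodulograms from intracranial EEG, in which each frequency-pair pixel
    encodes both the coupling strength (a Kullback-Leibler modulation index)
    and the coupled low-frequency phase as a single complex number.  Provides
    surrogate significance screening, a generator of synthetic coupled
    signals with class structure, a complex-valued convolutional neural
    network for classifying pathological versus normal coupling patterns,
    and channel-level evaluation with ROC/AUC, leave-one-patient-out
    cross-validation, band ablation, and real-valued baseline classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    e1071,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
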