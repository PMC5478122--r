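Package: seizecast
Title: Supervised Spectral Filters for Intracranial EEG Seizure Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Preprocessing and classification pipeline for preictal versus
    interictal discrimination in multichannel intracranial EEG. Implements
    supervised per-band spectral filters (difference of means, variance
    difference, variance-mean trade-off, second-moment difference and paired
    squared-difference objectives) estimated by matrix-free power iteration,
    alongside the conventional uniform power-band filter baseline. Provides
    sliding-window log-compressed FFT features, a distance-weighted K-nearest
    neighbour posterior with geometric clip-level aggregation,
    leave-one-seizure-out cross-validation, ROC/AUC reporting with DeLong
    paired AUC tests, and a synthetic iEEG generator with planted narrow-band
    class effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
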