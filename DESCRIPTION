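Package: somnark
Title: Sleep Architecture and Spectral Heart Rate Variability from Rodent Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, tidyverse-native pipeline for rodent
    polysomnography: sliding Hamming-window spectral features (mean power
    frequency, EMG band power, delta/theta/alpha/beta fractions) from EEG and
    EMG, histogram-threshold sleep staging into active waking, quiet sleep and
    paradoxical sleep, bout/interruption/transition architecture metrics, an
    ECG chain from R-peak detection through RR tachogram resampling to
    stage-conditioned low-frequency and high-frequency spectral heart rate
    variability, and normality-gated two-group statistics. A seeded
    synthetic-signal generator (semi-Markov hypnogram, band-structured EEG
    noise, integral-pulse-frequency-modulation ECG) provides ground-truth
    recordings so every stage of the chain is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
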