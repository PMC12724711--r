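Package: lucisync
Title: Circadian Rhythm Detection and Synchrony Analysis for
    Longitudinal Bioluminescence Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal PER2::LUC bioluminescence
    recordings from photomultiplier tubes, luminometers and cooled-camera
    image stacks. Provides detrending (time-based running mean, windowed-sinc
    filters), circadian rhythm detection and classification (Lomb-Scargle,
    rank-correlation template matching, harmonic regression, Fisher
    meta-combination, damped-cosine fitting), daily peak-time and
    peak-to-trough amplitude extraction, Morlet-wavelet instantaneous phase,
    Kuramoto order-parameter synchrony time courses, Rayleigh circular
    statistics, and end-to-end study runners. Includes a synthetic-data
    generator that emulates in utero photomultiplier traces, bioluminescence
    image stacks and tissue-explant recordings with known ground truth, so
    every estimator can be scored against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
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
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
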