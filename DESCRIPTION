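Package: sweepvep
Title: Sweep ssVEP Threshold Extraction and Reliability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating sensory thresholds from sweep steady-state
    visually evoked potential (ssVEP) recordings and for assessing their
    reliability. Implements the spectral pipeline for frequency-tagged sweep
    stimulation (single-bin discrete Fourier transform at the response
    frequency, noise-floor adjustment from neighbouring bins, z-scoring and
    signal-to-noise ratios), data-driven electrode selection, and two
    threshold rules: a significance-run criterion on z-scored amplitudes and
    a linear-extrapolation (vanishing-amplitude) regression method with phase
    validity checks. A QUEST adaptive staircase with cumulative-Gaussian
    psychometric fitting models the behavioural arm against simulated
    observers. A statistics battery provides modified z-score outlier
    removal, ICC(3,1) test-retest reliability and Spearman correlation
    reports. A synthetic-data generator produces sweep EEG recordings with
    known ground-truth thresholds and score tables with configurable
    reliability, so the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
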