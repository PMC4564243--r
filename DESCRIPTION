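Package: orcacall
Title: Synthesis, Measurement and Categorisation of Killer Whale Vocalisations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reproducible pipeline for analysing odontocete vocalisations of the
    kind recorded from killer whales (Orcinus orca): synthetic generation of
    frequency-modulated whistles, amplitude-pulsed burst-pulse sounds, transition
    calls and Gabor click trains; Hamming-window power spectrograms; automatic
    tonal-contour (ridge) extraction with harmonic-overtone and sideband detection;
    measurement of the ten standard call parameters (frequency extremes, start and
    end frequency, frequency range, duration, numbers of extrema and inflection
    points, frequency-modulation rate, sideband spacing); click-train detection with
    inter-click-interval, duration, spectral-peak and reflection statistics; and
    call-type categorisation by seeded k-means with silhouette-based selection of
    the number of call types. A machine-readable catalog of published per-call-type
    measurement ranges is included for validation and for sampling realistic
    feature vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
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
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
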