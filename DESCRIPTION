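Package: eegpla
Title: Power-Line Artifact Estimation and Removal for EEG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the amplitude, frequency and phase of mains (power-line)
    interference in single-channel EEG recordings with a two-point ratio-based
    interpolated-DFT spectrum correction, refined by a second correction pass on
    two spectral lines re-evaluated half a bin either side of the first-pass
    frequency so that both lines carry high amplitude. The fitted sinusoid is
    subtracted as a compensation signal, removing the artifact without the
    start-up transient and waveform distortion of a notch filter. Includes a
    causal IIR notch baseline, seeded Monte-Carlo benchmarking of the two
    estimators, synthetic signal generators (tones, Gaussian noise at a target
    SNR, band-limited EEG surrogate), delimited-text and EDF channel readers,
    ggplot2 visualisations and a small command-line interface.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
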