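Package: pulsewave
Title: Pulse Waveform Analysis of Fingertip Photoplethysmography Across
    Blood-Pressure Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-sensor fingertip photoplethysmography (PPG)
    pulse-wave analysis: a synthetic cohort simulator with a physiologic
    beat template (systolic wave, dicrotic notch, reflected wave), zero-phase
    band-pass preprocessing with an automated quality mask, valley-to-valley
    beat segmentation with fiducial detection, per-beat time-domain morphology
    and waveform-sharpness indices, pulse-rate-variability and FFT harmonic
    features, and a per-feature systolic-blood-pressure group comparison with
    Kruskal-Wallis/ANOVA gating, Dunn or Tukey post hoc tests, and
    epsilon-squared effect sizes. Tidyverse-native: data frames in, tibbles
    out, with broom-style tidiers and ggplot2 autoplot methods.
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
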