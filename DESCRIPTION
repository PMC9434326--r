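Package: circatrend
Title: Amplitude-Change Aware Rhythm Detection for Time-Course Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies circadian oscillations with changing
    amplitude in time-resolved omics matrices. Fits a damped harmonic
    oscillator model per feature by deterministic multi-start nonlinear
    least squares, classifies the amplitude-change (AC) coefficient into
    damped, harmonic and forced waveforms, and applies nested F-tests with
    Benjamini-Hochberg correction and a post-hoc circadian period window.
    A trend-model library (linear, exponential, oscillator, oscillator
    plus linear) and joint modeling of paired noisy/clean channels (for
    example proteome/transcriptome) recover oscillations that are
    undetectable in a noisy channel alone. Includes Fisher's exact
    enrichment of AC categories and biotypes, annotation-set overlap
    counting, and a synthetic-data generator emulating a dense circadian
    sampling design for recovery, power and type-I-error testing.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
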