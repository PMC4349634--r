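Package: eegsta
Title: Spike-Triggered Averaging and Forward Modelling of High-Frequency Epidural EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for estimating the surface-EEG correlate of a
    single cortical action potential from simultaneous micro-electrode and
    epidural-EEG recordings. Provides zero-phase Fourier-domain band-pass
    filtering with Gaussian-smoothed transitions, spike detection and
    minimum-separation pruning, spike-triggered EEG averaging with a
    shift-predictor (trial-shuffle) null and bootstrap peak tests, a
    log-spaced truncated-Hanning spectral estimator with bootstrap
    frequency-wise significance, Slepian multitaper power spectra, a
    closed-form model of the contribution of correlated neuronal
    populations (Mexican-hat kernel convolved with a Gaussian
    cross-correlogram), prediction of evoked high-frequency EEG bursts from
    post-stimulus time histograms, a dipole volume-conduction forward
    model, and a seeded synthetic-session generator that emulates the
    statistical structure of awake-primate recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
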