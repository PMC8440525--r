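Package: ssveprca
Title: Reliable Components Analysis for Frequency-Tagged EEG
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for steady-state visual evoked potential (SSVEP)
    oddball experiments: simulation of multichannel EEG with planted
    periodic sources, standard preprocessing (zero-phase bandpass,
    resampling, bad-sensor repair, average reference, epoch-level
    artifact rejection), extraction of complex Fourier coefficients at
    stimulation harmonics, Reliable Components Analysis (RCA) spatial
    filtering with forward-model topographies, Hotelling T-squared
    statistics on complex coefficients with false-discovery-rate
    correction, circular phase comparisons, and group-delay (apparent
    latency) estimation from the phase-versus-frequency slope.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
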