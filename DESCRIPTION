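Package: fdeeg
Title: Fractional-Diffusion Modelling of Evoked EEG Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the single-channel EEG response to an external stimulus
    as the solution of a fractional diffusion equation of temporal order 2H,
    where H is the Hurst exponent of the signal. Provides rescaled-range
    (R/S) Hurst estimation with sliding-window tracking, the Bessel-based
    time-dependent effective-diffusivity law of the phase-lagging diffusion
    model, evaluation of the Riemann-Liouville fractional-integral response
    to Gaussian-pulse stimuli by singularity-exact product integration, a
    seedable synthetic EEG trial generator with fractional-Gaussian-noise
    background, evoked-response feature extraction (initiation latency,
    duration, peak-to-peak voltage), signal input/output with bandpass and
    wavelet-shrinkage preprocessing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
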