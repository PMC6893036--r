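Package: respox
Title: Respiration-Modulated Cerebral Oxygenation: Analysis and Transport Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how respiration and neural activity shape
    cerebral oxygenation during locomotion. Implements treadmill-based
    locomotion event detection, zero-phase preprocessing of polarographic
    oxygen and electrophysiology channels, multitaper local field potential
    spectral analysis with fast-/regular-spiking waveform classification,
    intrinsic optical signal spectroscopy via the modified Beer-Lambert law,
    hemodynamic/neural response function estimation by Toeplitz least-squares
    deconvolution, cross-correlation with surrogate confidence bands, ordinary
    and partial coherence, phosphorescence-lifetime oximetry with
    respiration-phase-resolved arterial oxygen profiles and permutation
    significance tests, and an axisymmetric hemoglobin-buffered
    advection-diffusion-consumption model of oxygen exchange around a
    dilating cortical arteriole. A synthetic multimodal session generator
    with configurable ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
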