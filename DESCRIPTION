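Package: slscbf
Title: Short-Lag Spatial Coherence Beamforming for Fundamental and
    Harmonic Ultrasound
Version: 0.1.0
Authors@R:
    person("slscbf", "developers", email = "slscbf@example.org",
           role = c("aut", "cre"))
Description: Amplitude- and coherence-based beamforming of focused
    ultrasound radio-frequency channel data, including delay-and-sum
    (B-mode), short-lag spatial coherence (SLSC), lag-weighted M-SLSC,
    and robust-principal-component-analysis denoised r-SLSC and R-SLSC
    image formation for fundamental and pulse-inversion harmonic
    acquisitions.  Provides a point-scatterer channel-data simulator
    with controllable mass echogenicity and internal spatial coherence,
    reader-independent evaluation metrics (contrast, contrast
    difference, lag-one coherence, generalized contrast-to-noise
    ratio), threshold classification of fluid versus solid masses, and
    a configuration-driven pipeline that compares ten imaging modes on
    a labelled cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
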