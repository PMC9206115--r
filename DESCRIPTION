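Package: cortexwave
Title: Stochastic Reaction-Diffusion Modeling and Quantification of Cortical Rho GTPase Waves
Version: 0.1.0
Authors@R:
    person("cortexwave", "maintainers", email = "maintainers@cortexwave.invalid",
           role = c("aut", "cre"))
Description: Tools for the excitable-cortex circuit of Rho GTPase and F-actin:
    a three-field reaction-diffusion model with Ect2-dependent autocatalytic Rho
    activation and F-actin/RGA-3/4-dependent inactivation, integrated on 2D
    periodic lattices with spatially correlated multiplicative noise; linear
    stability analysis (dispersion relations, wave-instability and oscillatory
    regime classification along the negative-feedback axis); a wave
    quantification pipeline for time-lapse movies (box averaging,
    autocorrelation period, temporal width, relative amplitude,
    cross-correlation lag, kymographs); oscillation-phase reconstruction with
    topological phase-defect detection and tracking; morphological feature
    score histograms; and ground-truthed synthetic movie generators (plane
    waves, spirals, pulses, lagged follower channels) so the full pipeline is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
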