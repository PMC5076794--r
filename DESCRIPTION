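Package: bsb1map
Title: Bloch-Siegert B1+ Mapping for Multi-Peak 31P MR Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Phase-based radiofrequency transmit field (B1+) mapping for
    multi-peak X-nuclear magnetic resonance spectroscopy, built around the
    Bloch-Siegert shift. Provides Fermi sensitizing-pulse design by Bloch
    simulation grid search, four phase-based B1+ estimation strategies with
    analytic error propagation and Monte Carlo validation, Cramer-Rao lower
    bounds for spectral phase estimates, time-domain prior-knowledge fitting
    of damped Lorentzian 31P spectra, partial-saturation reference flip-angle
    methods (multi-TR, dual-TR, multi-flip-angle), and a surface-coil
    chemical shift imaging simulator with intravoxel isochromat analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
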