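Package: optoplace
Title: Analysis of All-Optical Place-Cell Perturbation Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantification pipeline for simultaneous two-photon calcium
    imaging and targeted photostimulation experiments in head-fixed mice
    navigating a virtual linear track. Covers fluorescence normalisation
    (sliding-percentile dF/F), velocity-filtered spatial tuning maps,
    place-field detection and zone classification, photostimulation
    response calling with off-target screening, behavioural spatial maps
    and deceleration statistics with block-shuffle nulls, latent-factor
    trajectory divergence with suppressed/enhanced cell calling, and
    pre/post place-field remapping with translation-shuffle nulls. Ships
    a synthetic session generator that emulates the task and the calcium
    data with planted ground truth so every stage is verifiable by
    construction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
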