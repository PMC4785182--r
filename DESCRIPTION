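Package: stepconn
Title: Movement-Locked EEG Spectral Perturbation and Directed Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multichannel EEG recorded during rhythmic
    limb movement (recumbent stepping and viewed stepping). Implements
    movement-cycle epoching with linear time-warping, event-related spectral
    perturbation (ERSP) with bootstrap significance masks, infomax
    independent component analysis with k-means component clustering,
    sliding-window multivariate autoregressive (MVAR) modelling via the
    Vieira-Morf lattice with stability and residual-whiteness diagnostics,
    directed transfer function (DTF) effective connectivity, suprathreshold
    pair statistics, and harmonic analysis of connectivity fluctuation at
    multiples of the stepping cadence. A ground-truth-known synthetic
    source-network generator (coupled stochastic resonators with
    cycle-phase-modulated directed gains, scalp mixing, sensor noise and
    transient artifacts) makes every stage testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
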