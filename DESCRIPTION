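Package: seqsecrete
Title: Sequential Multiplexed Single-Cell Secretion Analysis
Version: 0.1.0
Authors@R: person("seqsecrete", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of multiplexed, sequential protein-secretion
    measurements from the same single cells on antibody-barcode microtrough
    chips: zero-cell-well background gating, same-cell time-course assembly
    across antibody-slide exchanges, secretion-dynamics pattern
    classification, polyfunctionality statistics including the
    polyfunctionality index and basal-to-stimulated coupling, and two-state
    clustering of dynamic secretion profiles.  Includes a synthetic chip
    generator emulating the measurement process (Poisson well loading, two
    latent basal states, per-protein dynamic modes, per-exchange cell
    retention, lognormal signal over truncated-normal background) so every
    stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rtsne,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
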