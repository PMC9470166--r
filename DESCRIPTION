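Package: sipstruct
Title: Drinking Microstructure Analysis for Home-Cage Lickometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing rodent drinking microstructure recorded by
    home-cage lickometers during limited-access (drinking-in-the-dark)
    sessions. Segments beam-break event streams into drinking bouts using the
    device's two-second write rule, removes leak and chew artifacts by
    residuals of a licks-versus-duration linear model, extracts a canonical
    18-feature per-session microstructure vector, and classifies sessions by
    fluid and viral manipulation with a feedforward network under stratified
    k-fold cross-validation. Also computes standard slice-electrophysiology
    measurements (evoked amplitudes, AMPA/NMDA ratio, paired-pulse ratio,
    population spikes, spontaneous-event metrics, series-resistance quality
    control) and ships a seeded generative model of cohort drinking behavior
    and synaptic current sweeps so the whole pipeline is testable without any
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    readr,
    jsonlite,
    yaml
Suggests:
    withr,
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
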