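Package: lampanel
Title: Multi-Well Isothermal Amplification Panel Simulation and Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computational core for multi-well loop-mediated isothermal
    amplification (LAMP) diagnostic panels read out with quenching probes.
    Simulates per-well fluorescence quench traces for a 25-well chip with
    Poisson partitioning of low-copy template, calls per-well amplification
    times (Tt) from the minimum of the normalized differential curve,
    aggregates wells into item-level panel results with control validation
    and co-infection flagging, estimates limits of detection from
    dilution-series replicate grids by the all-negative-run step rule, and
    provides closed-form and Monte-Carlo Poisson occupancy models of
    per-well and per-item positivity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
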