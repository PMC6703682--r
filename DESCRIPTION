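Package: sardsim
Title: Bio-Economic Simulation of an Upwelling-Driven Small Pelagic Fishery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coupled climate-biology-economy modelling toolkit for an
    open-access artisanal purse-seine fishery on round sardinella
    (Sardinella aurita) off Senegal.  Computes coastal upwelling indices
    from wind stress, fits and simulates a climate-dependent logistic
    surplus-production model of the spawning stock, solves a monthly
    open-access market equilibrium built on iso-elastic demand and a
    Cobb-Douglas harvest technology with temperature-dependent
    catchability, and runs stochastic multi-decade ensembles that report
    population-viability (mean time of survival) and welfare (net present
    value of fisher and consumer surplus) metrics under
    business-as-usual versus fuel-subsidy-removal policy scenarios.
    Synthetic climate and biology generators make the full pipeline
    reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
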