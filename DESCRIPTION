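Package: redoxrelay
Title: Kinetic Modelling of Thiol-Disulfide Redox Regulation in the
    Chloroplast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mass-action kinetic simulation of the chloroplast
    thiol-disulfide redox relay (ferredoxin, ferredoxin-thioredoxin
    reductase, thioredoxins, 2-cysteine peroxiredoxin and redox-regulated
    target enzymes), with equilibrium constants of every thiol-disulfide
    exchange forced by the Nernst relation between midpoint potentials.
    Includes an event-driven simulator of coupled spectrophotometric
    enzyme assays (pre-activation, dilution, timed additions, A340
    readout), a light-to-dark transition model with clamped redox pools,
    quantification of activity traces (maximum-slope extraction, percent
    inhibition, exponential half-life fitting, residual activity,
    activation ratios), and seed-deterministic synthetic-data generators
    for end-to-end testing of the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
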