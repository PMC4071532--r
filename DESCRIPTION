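Package: megapast
Title: Macroecological Analysis of Late Quaternary Megafauna Extinctions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for global macroecological analysis of late
    Quaternary large-mammal extinctions. Computes climate-change anomaly and
    velocity surfaces from paired-epoch gridded climate fields, curates extinct
    species records and presence/absence ranges over a tessellation of analysis
    regions, estimates potential extant richness with a quasi-binomial
    human-impact correction, and models per-region extinction proportions with
    arcsine-square-root Gaussian models, quasi-binomial checks, AIC candidate
    selection, and spatial simultaneous autoregressive (SAR) error models with
    Moran's I correlogram diagnostics. A synthetic-world generator reproduces
    the statistical structure of the study system so every stage is verifiable
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
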