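Package: metaconn
Title: Metacommunity Beta Diversity, Locality Connectivity and Variation
    Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing metacommunity structure from site-by-species
    tables: pairwise Sorensen beta diversity partitioned into turnover and
    nestedness components, Hanski-style incidence-function connectivity
    metrics with dispersal-scale estimation, distance-based Moran's
    eigenvector maps as spatial predictors, Mantel correlograms, and
    three-set redundancy-analysis variation partitioning with Monte Carlo
    permutation tests. Includes a synthetic metacommunity generator with
    controlled species-sorting, dispersal-limitation and noise components
    so every pipeline stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
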