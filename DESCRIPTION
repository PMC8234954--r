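Package: radgrn
Title: Correlation Network Inference and Spectral Analysis of Radiation-Response Gene Modules
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers Pearson-correlation gene regulatory networks from small-replicate
    expression matrices with t-test significance filtering, extracts enriched process
    subnetworks with hub-gene detection, computes topological and algebraic spectral
    network measures (subgraph centrality, adjacency and normalized spectral gaps,
    girth, diameter, density, Jaccard neighborhood similarity), discovers per-gene
    Markov blankets with the incremental-association (IAMB) algorithm under Gaussian
    conditional-independence testing, and ranks hub genes by logistic regression on
    centrality features. Includes a synthetic-data generator emulating block-correlated
    gene modules with star-shaped hub neighborhoods and linear-Gaussian Bayesian
    networks, so the full pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
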