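Package: rmtnet
Title: Random Matrix Theory Based Microbial Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers microbial co-occurrence networks from OTU abundance
    tables using automatic, random-matrix-theory (RMT) based selection of
    the Pearson correlation threshold: the cutoff is placed where the
    nearest-neighbor spacing distribution of the thresholded similarity
    matrix's eigenvalues transitions from Gaussian-orthogonal-ensemble to
    Poisson statistics. Downstream tools separate modules by fast-greedy
    modularity optimization, classify keystone candidates by within-module
    degree (Zi) and among-module connectivity (Pi), relate modules to host
    physiology through module eigengenes, OTU significance and (partial)
    Mantel tests, and export Cytoscape-compatible networks. A synthetic
    community generator with known module, hub and trait-coupling ground
    truth makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    biomformat,
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
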