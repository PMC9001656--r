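Package: sludgenet
Title: Community Assembly Analysis for Activated-Sludge Microbiome Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing microbial community assembly in activated-sludge
    bioreactor time series from ASV count tables, sample metadata and a rooted
    phylogeny. Builds probabilistic co-occurrence/co-exclusion metawebs with an
    exact hypergeometric pairwise association model, detects modules with
    walktrap, tracks module completeness and per-sample network topology against
    stochastic block model nulls, quantifies phylogenetic dispersion (NRI/NTI)
    against taxa-shuffle nulls, computes Hill-number alpha diversity and
    Bray-Curtis dissimilarity, and correlates node abundances with pollutant
    removal rates under FDR control. Includes a synthetic-data generator that
    emulates seasonal alternation and start-up succession scenarios so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    mclust,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
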