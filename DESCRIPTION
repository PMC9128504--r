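Package: PhyloAssembly
Title: Phylogenetic Null Models for Microbial Community Assembly Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the ecological processes assembling microbial
    communities from amplicon feature tables and a phylogeny. Implements
    abundance-weighted phylogenetic community structure statistics (MPD,
    MNTD, beta-MNTD) with taxa-shuffle null models and their standardized
    effect sizes (NRI, NTI, beta-NTI), the Bray-Curtis-based Raup-Crick
    null (RC-bray), and the five-way partition of pairwise comparisons
    into heterogeneous selection, homogeneous selection, dispersal
    limitation, homogenizing dispersal, and drift/diversification.
    Includes alpha diversity (Pielou evenness, Simpson, ACE), internal
    standard (spike) normalization, a trait-based community simulator
    with known assembly regimes, and a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    vegan,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
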