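Package: micasa
Title: Microbial Community Assembly, Structure and Association Networks for Casing-Soil Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for casing-soil (and similar gradient-design)
    microbiome studies: alpha-diversity indices with group comparisons,
    Bray-Curtis ordination and permutation tests (PERMANOVA, ANOSIM, MRPP),
    core-taxon screening, phylogenetic null-model partitioning of community
    assembly into five ecological processes (beta-NTI and Raup-Crick on
    Bray-Curtis), correlation-threshold co-occurrence networks with topology,
    random-network nulls, robustness, vulnerability and Zi-Pi keystone
    classification, and environmental-driver attribution via partial Mantel
    tests and variance partitioning. Includes a synthetic community generator
    with controllable assembly regime, phylogenetic trait signal and
    environment coupling, so every stage can be exercised against known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
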