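Package: crustpool
Title: Species-Pool Biogeography, Assembly Processes, and Co-Occurrence
    Networks for Dryland Biocrust Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the biogeography of microbial communities
    sampled across a network of dryland biocrust plots, each treated as a
    species pool. Implements taxonomic (Bray-Curtis) and phylogenetic
    (weighted UniFrac) dissimilarities, permutation statistics (PERMANOVA,
    ANOSIM, Mantel), a combination-based driving-force framework that
    regresses factor explanations on geographic extent across constrained
    plot subsets, Stegen-style null-model partitioning of community assembly
    (betaNTI and Raup-Crick on Bray-Curtis), and co-occurrence network
    topology with Zi-Pi node-role classification. A synthetic-data module
    generates study designs, phylogenies, environmental gradients, and
    communities under known assembly regimes so that every stage of the
    pipeline can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    igraph,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
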