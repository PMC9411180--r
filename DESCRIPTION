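Package: skullnet
Title: Anatomical Network Analysis of Skull Articulation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anatomical network analysis (AnNA) of skulls and other
    jointed skeletal systems. Reads binary bone-articulation adjacency matrices,
    validates bilateral symmetry, and computes whole-network parameters (node and
    connection counts, density, mean clustering coefficient, mean shortest path
    length, connection heterogeneity, and parcellation from leading-eigenvector
    communities). Builds generalized topological overlap (GTOM) similarity
    matrices and UPGMA dendrograms, partitions them into Q-modules by
    Newman-Girvan modularity maximization over all dendrogram cuts, and annotates
    statistically supported S-modules with one-sided Mann-Whitney tests. Projects
    per-taxon parameter tables into a connectivity-based morphospace
    ("topospace") by ordinary and phylogenetic principal component analysis under
    Brownian motion, and tests group separation with (pairwise) PERMANOVA.
    Includes a generator of bilaterally symmetric skull-like networks with
    planted modules, pure-birth trees, and Brownian trait tables for simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    vegan,
    mclust,
    optparse
Config/testthat/edition: 3
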