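Package: endonet
Title: Bipartite Network Analysis of Host-Endophyte Metabarcoding Communities
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing quantitative bipartite interaction networks
    between plant hosts and their fungal endophytes as recovered by ITS
    metabarcoding. Converts per-MOTU sequence-similarity hits into
    rank-truncated taxonomic assignments using identity-threshold rules,
    builds host-by-taxon read-count interaction matrices, computes the
    standard battery of network-level indices (connectance, web asymmetry,
    NODF and weighted NODF nestedness, Bersier linkage density and weighted
    connectance, H2' specialization, checkerboard C-score, Horn niche
    overlap) and node-level indices (degree, species strength, weighted
    betweenness, effective partners, proportional generality), maximizes
    Barber's bipartite modularity by simulated annealing, and partitions
    taxa into trophic modes and guilds from a local guild database. A
    synthetic community generator with planted modular or nested structure
    and log-normal abundances makes every stage testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
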