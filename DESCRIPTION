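Package: ppitour
Title: Functional Module Detection in Protein Interaction Networks via
    Shortest Hamiltonian Path Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects protein functional modules (PFMs) in undirected
    protein-protein interaction networks. Proteins are embedded in a
    Czekanowski-Dice neighbourhood-distance space, ordered along a short
    Hamiltonian path found by a nearest-neighbour construction followed by
    Lin-Kernighan-style sequential K-opt improvement, and the path is then
    segmented into preliminary clusters. Clusters are merged by Gene
    Ontology annotation similarity, filtered by internal edge density, and
    scored with cohesion and separation validity indices. Includes a
    planted-partition synthetic network generator with matching GO term
    pools so the whole pipeline is testable without external data, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
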