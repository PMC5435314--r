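Package: anatnet
Title: Anatomical Network Analysis of Musculoskeletal Systems
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for anatomical network analysis (AnNA) of musculoskeletal
    systems: bones, muscles and fibrous (connective-tissue) knots are modeled
    as typed nodes of an undirected simple graph whose edges encode physical
    contacts (joints, ligaments, monoaxial tendons). Implements exact geodesic
    betweenness centrality (Brandes' algorithm), Newman-Girvan modularity
    under the standard configuration-model null and under constrained nulls
    for quasi-bipartite networks in which muscle-muscle contacts are forbidden,
    modularity maximization (exhaustive search for small graphs, greedy
    agglomeration with seeded local-moving refinement otherwise), partition
    comparison (adjusted Rand index, variation of information),
    Fruchterman-Reingold force-directed layout, degree-preserving edge
    rewiring, and generators of limb-like and planted-partition benchmark
    networks. Ships a published 54-node frog hindlimb network as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
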