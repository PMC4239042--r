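Package: overmod
Title: Converting Disjoint Network Partitions into Overlapping Communities
Version: 0.1.0
Authors@R:
    person("overmod", "maintainers", email = "overmod@example.org",
           role = c("aut", "cre"))
Description: Two-stage detection of overlapping community structure in
    undirected (optionally weighted) networks such as protein-protein
    interaction graphs.  Stage one takes any disjoint (hard) partition --
    from the built-in Louvain-style optimiser or an external tool -- and
    classifies nodes as isolated or connector.  Stage two maximises an
    overlapping-modularity objective over binary connector/module
    assignments by exact enumeration on small instances and seeded
    multi-start steepest-ascent local search in general, turning the hard
    partition into a soft partition in which connectors become inter- or
    intra-connectors.  Includes the participation coefficient and other
    node profiles, Jaccard stability comparison, Monte-Carlo node-removal
    robustness curves, and a planted-overlap synthetic benchmark generator
    with recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
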