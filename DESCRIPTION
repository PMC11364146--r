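Package: treecentroid
Title: Centroid Summary Trees for Ranked Phylogenies in RNNI Space
Version: 0.1.0
Authors@R:
    person("Sam", "Collins", email = "sam.collins@example.org",
           role = c("aut", "cre"))
Description: Summarises samples of ranked phylogenetic time trees (e.g.
    Bayesian posterior samples) by approximating their Frechet mean in the
    ranked nearest neighbour interchange (RNNI) treespace.  Provides the
    RNNI distance and shortest paths via the FindPath algorithm, a
    hill-descent Centroid search with a Sturm-style starting tree,
    rank-based branch-length annotation, a maximum clade credibility
    baseline with common-ancestor heights, summary-tree quality metrics
    (clade age/rank error, RNNI, Robinson-Foulds, weighted RF), synthetic
    tree-sample generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
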