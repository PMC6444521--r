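Package: groupnet
Title: Group-Representative Structural Brain Networks via Distance-Dependent
    Consensus Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs sparse group-representative structural connectivity
    networks from multi-subject cohorts of weighted adjacency matrices.
    Implements distance-dependent consensus thresholding, which retains the
    most consistently expressed connection within each bin of inter-node
    Euclidean distance so that the group network preserves the pooled
    subject-level edge-length distribution, alongside simple averaging and
    uniform consensus thresholds (fixed tau and density-matched tau) for
    comparison. Includes the standard battery of binary and weighted graph
    statistics (degree, strength, clustering, path length, efficiency,
    betweenness, modularity with a resolution parameter, participation,
    assortativity), Kolmogorov-Smirnov and z-score comparisons of group
    versus subject networks, within/between cognitive-system density analysis
    with permutation nulls, hub rank-redistribution analysis, a seeded
    synthetic cohort generator with distance-decaying connection probability,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
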