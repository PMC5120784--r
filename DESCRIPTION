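Package: hyperdfc
Title: Hypergraph Analysis of Dynamic Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds dynamic functional connectivity (DFC) hypergraphs from
    multi-region time series: band-pass filtering, non-overlapping sliding-window
    Pearson correlation networks, edge weight time series, an FDR-thresholded
    edge-edge correlation graph whose connected components are hyperedges, and
    summary metrics (hyperedge size, hypergraph cardinality, hyperedge node
    degree). Includes a temporal-shuffle null model, permutation tests for
    task-specific hyperedges, and an individual-differences stage with
    category-wise SVD factor reduction and hierarchical regressions reporting
    per-category R-squared changes. A synthetic-data generator plants groups of
    co-fluctuating node pairs (hyperedge-generating modules) and an age-linked
    fragmentation effect so the whole pipeline can be validated by parameter
    recovery.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
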