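Package: netpropel
Title: Out-of-Core Vertex-Centric Network Propagation for Multi-Species
    Protein Function Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Secondary-memory network learning for automated protein
    function prediction. Provides a sharded on-disk representation of
    large weighted protein networks with parallel-sliding-windows
    traversal, a synchronous vertex-centric execution engine, a local
    (per-vertex) implementation of the t-step random walk used to rank
    proteins by functional-class relevance, construction of data-type
    specific similarity networks from binary profiles (classical and
    hierarchical Jaccard), unweighted-average network integration,
    orthology-clique augmentation for multi-species networks, a
    stratified cross-validation evaluation harness (AUC, precision at
    recall, paired Wilcoxon tests), and deterministic synthetic-data
    generators emulating multi-species functional networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    methods,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
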