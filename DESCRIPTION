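Package: aphidcoex
Title: Morph-Specific Expression, Co-Expression Networks and Marker
    Discovery for Pea Aphid Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for multi-morph insect expression
    matrices: expressed-gene filtering on FPKM, the tau type-specificity
    index with strict-threshold specific-gene calls, highly-variable-gene
    selection by standard deviation, mutual-information co-expression
    network inference with data-processing-inequality pruning and
    core-gene (hub) detection, k-means expression-pattern clustering,
    and random-forest morph-marker ranking. Includes a synthetic
    expression-matrix generator with planted type-specific genes,
    co-expression modules with hubs, and morph markers, so every stage
    can be validated against a known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
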