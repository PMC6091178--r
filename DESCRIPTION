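Package: guideCoex
Title: Guide-Gene Co-Expression Screening for Candidate Regulator Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate transcription factors by guide-gene
    co-expression across an ordered developmental gradient transcriptome.
    Computes Pearson correlations between a set of anchor ("guide") genes of
    known function and all other genes, screens by absolute-correlation
    thresholds, ranks transcription-factor families by abundance among the
    strongly co-expressed genes, intersects top-ranked families across guides,
    builds a sign-stratified bipartite guide-TF co-expression network with
    Cytoscape-compatible (SIF, GraphML) export, and nominates putative
    negative regulators from the negative-edge structure. A synthetic
    gradient-transcriptome generator with planted correlation structure makes
    every stage testable without external data and supports recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
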