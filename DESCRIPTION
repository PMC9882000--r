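Package: hetpath
Title: Connectivity Search on Heterogeneous Biomedical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised connectivity search on heterogeneous information
    networks (hetnets). Computes degree-weighted path counts (DWPCs) between
    typed nodes by matrix multiplication with exact corrections for repeated
    nodes, generates degree-preserving permuted networks with the XSwap
    algorithm, pools permuted DWPCs into degree-grouped running summary
    statistics, fits a gamma-hurdle null distribution with empirical
    fallbacks, and ranks metapaths and individual paths connecting a pair of
    query nodes. Includes an on-disk store for hetnets with one biadjacency
    matrix per edge type, metapath enumeration and repeat-pattern
    segmentation, and deterministic synthetic network generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'hetpath-package.R'
    'metagraph.R'
    'metapath.R'
    'pattern.R'
    'hetnet.R'
    'dwpc.R'
    'permute.R'
    'nullmodel.R'
    'search.R'
    'fixtures.R'
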