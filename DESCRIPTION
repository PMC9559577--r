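Package: moduleEvo
Title: Multi-Stage Molecular Module Evolution Networks from Seeded Random Walks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies molecular modules in stage-specific heterogeneous
    networks of genes, miRNAs and lncRNAs using Monte-Carlo random walks with
    linearly decaying step weights and a degree-based penalty, screens
    high-weight vertices into connected modules, links modules within stages
    by cross-edge counts and across adjacent stages by Jaccard similarity,
    annotates modules by hypergeometric over-representation against GMT gene
    sets with Benjamini-Hochberg control, and distils the combined module and
    function networks into a core evolution network. Includes a planted-module
    synthetic data generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
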