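Package: cbnet
Title: Causal Biological Network Models from BEL Statements with
    Transcriptomics-Based Node Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parse causal statements written in a Biological Expression
    Language (BEL) subset, compile them into signed two-layer causal network
    models (an entity backbone plus a downstream mRNA layer), harmonize gene
    nomenclature across species via ortholog maps, and infer the activity of
    backbone nodes from differential gene-expression contrasts using a signed
    concordance statistic with permutation significance. Includes a synthetic
    data generator with known ground truth, Cytoscape-oriented SIF/GraphML
    export, a lossless JSON model format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
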