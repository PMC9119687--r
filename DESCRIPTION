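Package: oncographnn
Title: Attention-Propagation Graph Neural Networks for Kinase-Inhibitor
    Response Prediction in Cancer Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates protein-protein interaction networks with
    differential gene expression, disease-gene association scores, kinase
    inhibitor profiling, and growth-rate inhibition measurements into one
    annotated graph per (cell line, drug) combination; compacts each graph
    with a biology-driven node-merging procedure that enriches kinase-node
    density; and classifies the drug response (cytotoxic versus cytostatic)
    with a graph neural network built from attention-based propagation
    blocks, jumping-knowledge max-pooling, and a Set2Set readout.  Includes
    leave-one-tissue-out cross-validation, a synthetic-data generator with
    a planted label mechanism for benchmarking, and tidy accessors for all
    fitted objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
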