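Package: diffslc
Title: Coexpression-Biased Centrality for Essential Protein Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts essential proteins from a protein-protein interaction
    (PPI) network by biasing node centrality with gene-coexpression and
    edge-clustering-coefficient edge weights. Implements the DiffSLC score
    (an omega-weighted mix of eigenvector centrality and a beta-weighted
    coexpression/edge-clustering biased degree centrality), the reference
    centralities it is compared against (degree, closeness, betweenness,
    eigenvector, subgraph), three pairwise coexpression measures (Pearson,
    Spearman, distance correlation), readers for PSI-MI MITAB 2.5
    interaction files, expression matrices, probeset annotation tables and
    essential-gene lists, a ranking-evaluation layer (ROC/AUC,
    precision-recall, top-k percent hit counts, beta/omega parameter
    sweeps), and a coupled synthetic-fixture generator so the whole
    pipeline is testable without downloads.
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
    igraph,
    Matrix,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
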