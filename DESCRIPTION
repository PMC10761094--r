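Package: drfusion
Title: Drug Repositioning with Adaptive Dual-Space Graph Convolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-disease associations by learning drug and disease
    embeddings in two complementary spaces: a k-nearest-neighbour feature graph
    built from drug-drug and disease-disease similarity matrices, and the
    bipartite association topology graph processed with edge-type-specific
    message passing. The two embeddings are fused per node with learned
    attention weights, regularised by a consistency constraint on their cosine
    similarity structures, and scored pairwise with a multilayer perceptron.
    Includes dataset loaders for dense and sparse matrix formats, a planted
    low-rank synthetic data generator, repeated k-fold cross-validation over
    all pairs, a cold-start (new drug) protocol, component ablations,
    hyperparameter sweeps and attention reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    readr,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
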