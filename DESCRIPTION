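Package: dnalm
Title: Overlapping k-mer Tokenization and Desk-Scale Genomic Language Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating small DNA language models on
    prokaryotic sequence data. Implements local context-aware (LCA)
    tokenization of DNA into overlapping k-mers with a configurable shift,
    leakage-aware masked-language-model batch construction, order-o nucleotide
    Markov chains for compositional background sequences, builders for
    promoter and phage/host benchmark datasets (balanced negatives,
    leakage-excluded splits, genus-level base-pair balancing), an
    attention-weighted pooling classification head on top of a compact CPU
    transformer encoder, and an evaluation suite (MCC, F1, ROC-AUC,
    silhouette, masked-token restoration ranks). A synthetic genome generator
    makes every component testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    cluster,
    glmnet,
    jsonlite
Config/testthat/edition: 3
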