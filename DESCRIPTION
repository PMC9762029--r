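Package: sctriad
Title: Single-Cell Expression Analysis for a Triplicated Brassica Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell RNA-seq UMI count data from a
    whole-genome-triplicated crop genome with three homoeologous subgenomes
    (least-, medium- and most-fractionated: LF, MF1, MF2) plus ungrouped
    genes. Provides 10x-style MatrixMarket input/output, quality-control
    filtering and log-normalization, cluster composition and annotation,
    a two-part hurdle test for single-cell differential expression,
    cluster-enriched and cell-type marker calling, subgenome
    expression-dominance classification over syntelog groups, per-cell-type
    heat-stress differential expression with shared/specific/opposite
    partitioning, and a seeded negative-binomial simulator that emits
    ground truth for recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
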