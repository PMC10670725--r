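Package: miRcircuit
Title: miRNA-mRNA-Protein Regulatory Circuit Analysis for Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative multi-omics pipeline for identifying mechanism-typed
    miRNA-mRNA-protein regulatory circuits in tumor versus normal tissue.
    Provides negative-binomial differential expression with median-of-ratios
    normalization, directional overlap of differentially expressed genes and
    proteins, assembly of repressive (degradation and translational-repression)
    and inductive regulatory circuits from validated miRNA-target interactions,
    hub detection by maximal clique centrality and out-degree with tie
    expansion, hypergeometric over-representation analysis, and
    clinicopathological association statistics (ROC/AUC, quartile-stratified
    Kaplan-Meier survival with log-rank tests, Kruskal-Wallis/Mann-Whitney
    stage comparisons, and Pearson regulator-target correlation). A synthetic
    data generator with planted effects supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
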