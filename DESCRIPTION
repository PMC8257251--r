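Package: cafnet
Title: Stage-Specific Fibroblast Signatures, Enrichment Consolidation, and
    Transcription-Factor Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for profiling transcriptional rewiring of
    metastasis-associated fibroblasts across disease stages from bulk RNA-seq
    counts. Implements count filtering, quantile normalization with expression
    flooring, coefficient-of-variation exclusion, fold-change signature
    selection with protein-protein-interaction network pruning, hypergeometric
    over-representation analysis with cross-database term consolidation, gene
    set enrichment analysis with gene-set permutation, and a multi-evidence
    transcription-factor centrality ranking that consolidates network,
    regulon, and relatedness parameters by Z-scores with ANOVA/Tukey
    statistics. Ships a negative-binomial synthetic-data generator with
    planted ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
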