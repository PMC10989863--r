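Package: germscreen
Title: Marker-Anchored Candidate-Gene Prioritization from Single-Cell
    Ovary Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate germline genes from multi-replicate
    single-cell RNA-seq count data of the Drosophila ovary. Germline cells
    are labeled from the expression of four marker genes (vasa and the
    synaptonemal-complex genes c(3)G, cona and corolla), positively enriched
    genes are found per analysis by a tie-corrected Wilcoxon rank-sum test
    with Bonferroni correction, and candidates are aggregated across
    analyses by intersection followed by mean-rank ordering with a mean
    log-fold-change-rank tie-break, gene-class culling and top-N selection.
    Includes hypergeometric GO over-representation of the candidate list, a
    rule engine that turns per-germarium cytology scores into line- and
    gene-level phenotype tallies for the downstream RNAi screen, and a
    negative-binomial synthetic-data generator with ground truth so the
    whole pipeline can be exercised and validated without external data.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
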