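Package: immunopanel
Title: Targeted Immune Panel Expression Analysis for nCounter-Style Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for targeted immune gene-expression
    panels measured as digital probe counts (nCounter-style RCC lanes or plain
    count matrices). Provides background subtraction against negative-control
    probes, positive-control and geNorm housekeeping normalization, per-gene
    differential expression with Benjamini-Hochberg adjustment, gene-set global
    and directed significance scores, per-sample pathway Z-scores, marker-gene
    immune cell profiling with permutation confidence tests, pathway-phenotype
    Spearman correlation screens, hierarchical clustering and PCA summaries,
    Markov clustering of gene-interaction networks, and a seeded synthetic-data
    generator that emulates a treated-vs-vehicle time-course study design for
    testing every stage against known ground truth.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
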