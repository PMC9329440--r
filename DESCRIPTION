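Package: prsconcord
Title: Agreement Between Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how far two polygenic risk scores (PRS)
    for the same disease agree in the risk they assign to individuals.
    Computes per-individual scores from PGS-Catalog-style scoring files and
    genotype dosages, applying standard variant quality control (palindromic
    SNP removal, minor-allele-frequency and imputation-quality filters) and
    allele harmonization; quantifies variant overlap between two scores
    including linkage-disequilibrium proxies; and measures between-score
    agreement via Pearson correlation, seven-bin percentile
    cross-classification, top-k percent concordance, odds ratios against the
    middle quintile, crude and covariate-adjusted AUC, continuous and
    categorical net reclassification indices, and bootstrap confidence
    intervals. Includes a synthetic-cohort generator with LD-block-structured
    dosages and a closed-form bivariate-normal tail-concordance oracle, so
    the full pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
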