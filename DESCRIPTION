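Package: radpath
Title: Radiomic-Pathway Association Pipeline for Zone-Resolved Glioblastoma Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links MRI-subcompartment radiomic features to transcriptomic
    pathway programs scored from zone-level glioblastoma expression data.
    Provides single-sample gene-set enrichment scoring of FPKM expression,
    anatomic-zone to MRI-subcompartment mapping and aggregation, three-stage
    radiomic feature reduction (near-zero-variance, correlation pruning,
    supervised Spearman screening), per-pathway linear mixed-effects
    association with Nakagawa R2 decomposition, leakage-free nested
    leave-one-patient-out cross-validated elastic net prediction with in-fold
    feature selection, patient-level and fully nested permutation tests,
    conservative padded Benjamini-Hochberg corrections, Riley minimum-sample-size
    calculations, pre-specified sensitivity variants, and a synthetic-cohort
    generator that emulates the unbalanced repeated-measures design the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    caret,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
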