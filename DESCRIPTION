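Package: gmimmune
Title: Probiotic Immunomodulation Screening Analysis in Galleria mellonella
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-course qRT-PCR screens of probiotic
    immunomodulation in the Galleria mellonella infection model: larval
    health-index scoring and survival summaries, per-replicate 2^-ddCt
    relative expression with fold-change banding, normality-gated group
    testing (ANOVA/Tukey vs Kruskal-Wallis/Dunn-Bonferroni), cross- and
    within-treatment Spearman co-expression with strength categories and
    hierarchical clustering, and rule-based conservative consensus
    derivation from pairwise insect-human protein alignments. Includes
    synthetic-data generators that emulate the study design so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    car,
    dplyr,
    jsonlite,
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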