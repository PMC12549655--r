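#!/usr/bin/env Rscript
# Hypothesis testing over the reported comparison set: consecutive time
# points within each probiotic arm and LP-vs-LK at matched times, routed
# through the normality-gated branch (Shapiro-Wilk + Levene -> ANOVA/Tukey,
# otherwise Kruskal-Wallis + Dunn-Bonferroni), with star labels.
# Reads results/tables/expression.csv; writes results/tables/comparison_tests.csv.

suppressPackageStartupMessages(library(gmimmune))

design <- default_design()
expr <- readr::read_csv("results/tables/expression.csv", show_col_types = FALSE)
comparisons <- build_comparison_set(design)
res <- test_group_differences(expr, comparisons)
readr::write_csv(res, "results/tables/comparison_tests.csv")

cat(sprintf("%d comparisons (%d consecutive-time, %d between-treatment)\n",
            nrow(res),
            sum(res$kind == "consecutive_within_treatment"),
            sum(res$kind == "between_treatments_same_time")))
cat("\nbranch usage:\n"); print(table(res$branch))
cat("\nstar labels:\n"); print(table(res$stars))
sig <- res[res$stars != "ns", ]
cat(sprintf("\n%d significant contrasts; strongest:\n", nrow(sig)))
print(as.data.frame(sig[order(sig$p)[seq_len(min(5, nrow(sig)))], ]), digits = 3)
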