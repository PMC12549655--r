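#!/usr/bin/env Rscript
# Simulate one full screening dataset with the default study layout:
# ten immune genes, LP/LK probiotic arms vs PBS control, five times,
# 3 x 2 replicates. Injected fold-change trajectories give each gene a
# distinct temporal signature (transient mid-course induction for the
# NF-kB-like regulators, an early antimicrobial-peptide burst, a
# late-declining effector), so every downstream stage has structure to find.
# Outputs: results/data/{ct_table,health_observations}.csv and one synthetic
# aligned protein pair per gene under results/data/alignments/.

suppressPackageStartupMessages(library(gmimmune))
dir.create("results/data/alignments", recursive = TRUE, showWarnings = FALSE)
seed <- 1L

design <- default_design()
times <- design$times_h

# per-gene trajectories (fold change vs PBS) for the LP arm; the LK arm gets
# the same shape damped towards 1 to emulate a weaker strain response
lp_traj <- list(
  "Dorsal"          = c(0.5, 1.7, 3.8, 1.2, 0.8),
  "Rel"             = c(1.2, 2.0, 6.7, 0.3, 0.6),
  "cad"             = c(1.1, 2.3, 1.8, 0.6, 0.8),
  "18w"             = c(0.4, 0.05, 0.7, 0.3, 0.2),
  "spz4"            = c(0.9, 1.5, 0.4, 0.3, 0.3),
  "gallerimycin"    = c(2.0, 9.0, 39.5, 30.3, 13.1),
  "gloverin"        = c(6.0, 19.2, 8.0, 3.0, 1.5),
  "NADPH oxidase 4" = c(1.1, 2.5, 3.0, 3.7, 3.1),
  "Hem"             = c(1.8, 2.4, 0.6, 0.9, 0.8),
  "IMPI"            = c(0.9, 0.7, 0.8, 0.07, 0.08)
)
damp <- function(fc) 1 + (fc - 1) * 0.6
fc_tab <- dplyr::bind_rows(lapply(names(lp_traj), function(g) {
  dplyr::bind_rows(
    tibble::tibble(gene = g, treatment = "LP", time_h = times, fc = lp_traj[[g]]),
    tibble::tibble(gene = g, treatment = "LK", time_h = times, fc = damp(lp_traj[[g]]))
  )
}))
profiles <- effect_profiles(design, fc = fc_tab)

ct <- generate_ct_table(design, profiles, seed = seed)
write_ct_csv(ct, "results/data/ct_table.csv")
readr::write_csv(profiles$fc, "results/data/injected_fold_changes.csv")

# a healthy cohort with mild observer noise: the sub-lethal inoculum scenario
health <- generate_health_observations(
  design, health_profile(), seed = seed + 1L, n_larvae = 10, p_misread = 0.05)
readr::write_csv(health, "results/data/health_observations.csv")

# synthetic insect-vs-human alignment pairs, one per gene, with conservation
# rates spanning distant (35% identity) to close (60%) homology
idents <- seq(0.35, 0.6, length.out = length(design$target_genes))
for (i in seq_along(design$target_genes)) {
  pair <- generate_alignment_pair(300, p_identity = idents[i],
                                  p_conservative = 0.2, p_gap = 0.1,
                                  seed = seed + 10L + i)
  safe <- gsub("[^A-Za-z0-9]+", "_", design$target_genes[i])
  write_aligned_pair(pair, sprintf("results/data/alignments/%s.fasta", safe))
}

cat("simulated:", nrow(ct), "Ct rows,", nrow(health), "health records,",
    length(design$target_genes), "alignment pairs\n")
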