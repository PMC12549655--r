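#' Published cross-treatment correlation table
#'
#' The study's reported gene-wise Spearman coefficients comparing temporal
#' expression patterns between the two probiotic arms, with the printed
#' two-sided p-values (significant rows were printed as "<0.001"; the `p`
#' column carries that bound) and the printed strength category. Used as an
#' input when checking that the strength-band rules reproduce the printed
#' categories.
#'
#' @return Tibble `gene, rho, p, category`.
#' @export
published_cross_treatment_correlations <- function() {
  tibble::tribble(
    ~gene,              ~rho,   ~p,     ~category,
    "Dorsal",           0.9693, 0.001,  "strong",
    "Rel",              0.8888, 0.001,  "strong",
    "cad",              0.9240, 0.001,  "strong",
    "18w",              0.6917, 0.001,  "moderate",
    "spz4",             0.8115, 0.001,  "strong",
    "gallerimycin",     0.4633, 0.001,  "weak",
    "gloverin",         0.8976, 0.001,  "strong",
    "NADPH oxidase 4",  0.2010, 0.201,  "none",
    "Hem",              0.8798, 0.001,  "strong",
    "IMPI",             0.0880, 0.088,  "none"
  )
}

#' Fold-change recovery under measurement noise
#'
#' Monte-Carlo study of ddCt estimator accuracy: for each injected fold
#' change, simulate the qPCR experiment across independent seeds, run the
#' full relative-expression pipeline, and compare the across-seed mean of
#' the per-cell mean 2^-ddCt against the injected value.
#'
#' One compact design is used per run: one gene per fold change, one
#' active treatment plus control, one time point, `n_bio` biological x 2
#' technical replicates.
#'
#' @param fc_values Injected fold changes.
#' @param n_seeds Number of simulated experiments (default 200).
#' @param noise_sd Biological Ct noise SD (default 0.1).
#' @param tech_sd Technical Ct noise SD (default 0.05).
#' @param n_bio Biological replicates (default 3).
#' @param seed Base seed; simulation i uses `seed + i`.
#' @return Tibble `fc, mean_recovered, rel_bias` (relative bias,
#'   `mean_recovered / fc - 1`).
#' @export
simulate_fc_recovery <- function(fc_values = c(0.25, 0.5, 1, 2, 4, 39.5),
                                 n_seeds = 200, noise_sd = 0.1,
                                 tech_sd = 0.05, n_bio = 3, seed = 1) {
  genes <- sprintf("g%02d", seq_along(fc_values))
  design <- experiment_design(genes, "hk", "TRT", "CTRL",
                              times_h = 12, n_bio = n_bio, n_tech = 2L)
  fc_tab <- tibble::tibble(gene = genes, treatment = "TRT", time_h = 12,
                           fc = fc_values)
  profiles <- effect_profiles(design, fc = fc_tab,
                              noise_sd = noise_sd, tech_sd = tech_sd)
  acc <- matrix(0, n_seeds, length(fc_values))
  for (i in seq_len(n_seeds)) {
    ct <- generate_ct_table(design, profiles, seed = seed + i)
    expr <- compute_relative_expression(ct, "hk", "CTRL")
    m <- expr |>
      dplyr::filter(.data$treatment == "TRT") |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(mean = mean(.data$rel_expr), .groups = "drop")
    acc[i, ] <- m$mean[match(genes, m$gene)]
  }
  tibble::tibble(fc = fc_values,
                 mean_recovered = colMeans(acc),
                 rel_bias = colMeans(acc) / fc_values - 1)
}

#' Empirical type-I error of the gated testing branch
#'
#' Simulates null experiments (all fold changes 1, Gaussian Ct noise) and
#' runs the full normality-gated branch; the empirical type-I error is the
#' fraction of reported pairwise p-values below `alpha`. Each null dataset
#' uses a design whose comparison families are elementary two-group tests
#' (one gene, two active arms, two time points, 3 biological replicates),
#' so the per-comparison rejection rate is directly interpretable as alpha:
#' in multi-group families the Tukey/Dunn familywise correction deflates
#' per-pair error by design.
#'
#' By default the rate is measured on the between-treatment contrasts,
#' where the two groups share the same time-matched control baseline and
#' the branch's independence premise holds. Consecutive-time contrasts on
#' ddCt data are *structurally* anti-conservative -- each group carries its
#' own noisy control-arm mean as a shared additive error, inflating
#' between-group variance relative to within-group variance -- so their
#' rejection rate exceeds nominal for any two-sample test applied to
#' relative expression; set `kind = "consecutive_within_treatment"` to
#' measure that inflation.
#'
#' @param n_datasets Number of simulated null experiments (default 2000).
#' @param alpha Nominal level (default 0.05).
#' @param noise_sd Biological Ct noise SD (default 0.15).
#' @param seed Base seed.
#' @param kind Which comparison kind the rate is computed over.
#' @return List: `rate` (empirical alpha), `n_tests`, `n_datasets`,
#'   `branch_share` (fraction routed to the non-parametric branch).
#' @export
simulate_type1_error <- function(n_datasets = 2000, alpha = 0.05,
                                 noise_sd = 0.15, seed = 1,
                                 kind = "between_treatments_same_time") {
  kind <- match.arg(kind, c("between_treatments_same_time",
                            "consecutive_within_treatment"))
  design <- experiment_design("g1", "hk", c("LP", "LK"), "PBS",
                              times_h = c(3, 6), n_bio = 3L, n_tech = 2L)
  profiles <- effect_profiles(design, fc = 1, noise_sd = noise_sd,
                              tech_sd = 0.1)
  comparisons <- dplyr::filter(build_comparison_set(design), .data$kind == !!kind)
  pvals <- numeric(0)
  nonpar <- 0L
  total <- 0L
  for (i in seq_len(n_datasets)) {
    ct <- generate_ct_table(design, profiles, seed = seed + i)
    expr <- compute_relative_expression(ct, "hk", "PBS")
    res <- test_group_differences(expr, comparisons, alpha = alpha)
    pvals <- c(pvals, res$p)
    nonpar <- nonpar + sum(res$branch == "kruskal_dunn_bonferroni")
    total <- total + nrow(res)
  }
  list(rate = mean(pvals < alpha), n_tests = length(pvals),
       n_datasets = n_datasets, branch_share = nonpar / total)
}

#' Recovery of injected co-expression modules by clustering
#'
#' Simulates experiments in which the target genes split into two modules
#' sharing a common fold-change trajectory (one peaked, one monotonically
#' decreasing), plus Ct noise; runs the expression and correlation stages;
#' cuts the 1 - rho average-linkage tree at two clusters; and scores module
#' membership accuracy (best label matching) per seed.
#'
#' @param n_seeds Number of simulated experiments (default 100).
#' @param noise_sd Biological Ct noise SD (default 0.2).
#' @param n_genes Total genes, split evenly into two modules (default 10).
#' @param linkage Linkage passed to [cluster_correlation_matrix()].
#' @param seed Base seed.
#' @return List: `accuracy` (mean over seeds), `per_seed` vector, `n_seeds`.
#' @export
simulate_module_recovery <- function(n_seeds = 100, noise_sd = 0.2,
                                     n_genes = 10, linkage = "average",
                                     seed = 1) {
  stopifnot(n_genes >= 4, n_genes %% 2 == 0)
  half <- n_genes / 2
  genes_a <- sprintf("modA_%02d", seq_len(half))
  genes_b <- sprintf("modB_%02d", seq_len(half))
  times <- c(3, 6, 12, 18, 24)
  design <- experiment_design(c(genes_a, genes_b), "hk", "LP", "PBS",
                              times_h = times, n_bio = 3L, n_tech = 2L)
  traj_a <- c(1, 2, 6, 3, 1.5)    # transient induction peaking mid-course
  traj_b <- c(4, 2, 1, 0.5, 0.25) # monotone decline
  fc_tab <- dplyr::bind_rows(
    tidyr::expand_grid(gene = genes_a, treatment = "LP",
                       tibble::tibble(time_h = times, fc = traj_a)),
    tidyr::expand_grid(gene = genes_b, treatment = "LP",
                       tibble::tibble(time_h = times, fc = traj_b))
  )
  profiles <- effect_profiles(design, fc = fc_tab, noise_sd = noise_sd,
                              tech_sd = 0.1)
  truth <- c(stats::setNames(rep(1L, half), genes_a),
             stats::setNames(rep(2L, half), genes_b))
  acc <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    ct <- generate_ct_table(design, profiles, seed = seed + i)
    expr <- compute_relative_expression(ct, "hk", "PBS")
    mat <- within_treatment_matrix(expr, "LP")
    tree <- cluster_correlation_matrix(mat, linkage = linkage)
    cl <- cut_modules(tree, 2)
    tr <- truth[names(cl)]
    direct <- mean(cl == tr)
    acc[i] <- max(direct, 1 - direct)
  }
  list(accuracy = mean(acc), per_seed = acc, n_seeds = n_seeds)
}
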