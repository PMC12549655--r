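test_that("Spearman implementation agrees with the counting-rank oracle", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(3:6, 1)
    # draws with deliberate ties about half the time
    x <- if (i %% 2 == 0) sample(1:3, n, replace = TRUE) + 0 else rnorm(n)
    y <- if (i %% 3 == 0) sample(1:3, n, replace = TRUE) + 0 else rnorm(n)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    st <- spearman_test(x, y)
    expect_equal(st$rho, spearman_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("Spearman handles perfect, reversed and hand-computed rankings", {
  expect_equal(spearman_test(1:5, (1:5)^2)$rho, 1)
  expect_equal(spearman_test(1:5, rev(1:5))$rho, -1)
  # sum of squared rank differences 4 -> rho = 1 - 6*4/(5*24) = 0.8
  st <- spearman_test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(st$rho, 0.8, tolerance = 1e-12)
  expect_equal(st$method, "exact_permutation")
  # exact p: permutations of 5 ranks with |rho| >= 0.8 (16 of 120)
  expect_equal(st$p, 16 / 120, tolerance = 1e-12)
  expect_equal(spearman_test(rnorm(12), rnorm(12))$method, "t_approximation")
  expect_true(is.na(spearman_test(rep(1, 5), 1:5)$rho))
})

test_that("correlation strength bands reproduce the published category mapping", {
  expect_equal(classify_correlation_strength(0.4633, 1e-4), "weak")
  expect_equal(classify_correlation_strength(0.6917, 1e-4), "moderate")
  expect_equal(classify_correlation_strength(0.2010, 0.201), "none")
  # significance overrides magnitude
  expect_equal(classify_correlation_strength(0.95, 0.2), "none")
  # banded on magnitude; sign carried separately
  expect_equal(classify_correlation_strength(-0.75, 1e-4), "strong")
  pub <- published_cross_treatment_correlations()
  expect_identical(classify_correlation_strength(pub$rho, pub$p), pub$category)
})

test_that("cross-treatment correlation pairs replicates by time and errors on mismatch", {
  # identical temporal profiles under both arms -> rho 1
  base <- tibble::tibble(gene = "g", time_h = rep(c(3, 6, 12), each = 2),
                         bio_rep = rep(1:2, 3), rel_expr = c(1, 1.2, 2, 2.1, 4, 4.4))
  expr <- dplyr::bind_rows(dplyr::mutate(base, treatment = "LP"),
                           dplyr::mutate(base, treatment = "LK"))
  r <- cross_treatment_correlation(expr, "g", "LP", "LK")
  expect_equal(r$rho, 1)
  expect_equal(r$n, 6)

  rev_expr <- dplyr::bind_rows(
    dplyr::mutate(base, treatment = "LP"),
    dplyr::mutate(base, treatment = "LK", rel_expr = rev(.data$rel_expr)))
  expect_equal(cross_treatment_correlation(rev_expr, "g", "LP", "LK")$rho, -1)

  broken <- expr[-2, ]
  expect_error(cross_treatment_correlation(broken, "g", "LP", "LK"), "unmatched")
})

test_that("within-treatment matrices are symmetric with unit diagonal and honest masks", {
  genes <- c("gA", "gB", "gC")
  vals <- list(gA = c(1, 2, 3, 4, 5, 6), gB = c(2, 1, 4, 3, 6, 5),
               gC = c(6, 5, 4, 3, 2, 1))
  expr <- dplyr::bind_rows(lapply(genes, function(g) {
    tibble::tibble(gene = g, treatment = "LP", time_h = rep(c(3, 6, 12), each = 2),
                   bio_rep = rep(1:2, 3), rel_expr = vals[[g]])
  }))
  m <- within_treatment_matrix(expr, "LP")
  expect_equal(diag(m$rho), rep(1, 3), ignore_attr = TRUE)
  expect_identical(m$rho, t(m$rho))
  expect_identical(m$p, t(m$p))
  expect_false(any(diag(m$mask)))
  # every off-diagonal entry equals the brute-force oracle
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(m$rho[genes[i], genes[j]],
                 spearman_oracle(vals[[genes[i]]], vals[[genes[j]]]),
                 tolerance = 1e-12)
  }
  expect_true(all(m$mask[m$p < 0.05 & row(m$p) != col(m$p)]))

  const <- dplyr::bind_rows(expr, tibble::tibble(
    gene = "gD", treatment = "LP", time_h = rep(c(3, 6, 12), each = 2),
    bio_rep = rep(1:2, 3), rel_expr = 1))
  expect_warning(m2 <- within_treatment_matrix(const, "LP"), "constant")
  expect_true(all(is.na(m2$rho["gD", c("gA", "gB", "gC")])))
  expect_false(any(m2$mask["gD", ]))
})

test_that("shared noiseless trajectories correlate perfectly and cluster at height zero", {
  d <- experiment_design(c("gA", "gB", "gC"), "hk", "LP", "PBS", c(3, 6, 12))
  pr <- effect_profiles(d, noise_sd = 0, tech_sd = 0)
  traj <- c(1, 4, 2)
  for (g in c("gA", "gB")) pr <- set_fc(pr, g, "LP", c(3, 6, 12), traj)
  pr <- set_fc(pr, "gC", "LP", c(3, 6, 12), c(4, 1, 0.5))
  ct <- generate_ct_table(d, pr, seed = 3)
  expr <- compute_relative_expression(ct, "hk", "PBS")
  m <- within_treatment_matrix(expr, "LP")
  expect_equal(m$rho["gA", "gB"], 1, tolerance = 1e-9)
  expect_true(m$mask["gA", "gB"])
  tree <- cluster_correlation_matrix(m)
  expect_equal(tree$hclust$height[1], 0, tolerance = 1e-9)
  cl <- cut_modules(tree, 2)
  expect_equal(cl[["gA"]], cl[["gB"]])
  expect_false(cl[["gA"]] == cl[["gC"]])
})

test_that("clustering merges the closest genes first and ignores input order", {
  rho <- matrix(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- cluster_correlation_matrix(rho)
  first_pair <- sort(tree$hclust$labels[-tree$hclust$merge[1, ]])
  expect_equal(first_pair, c("A", "B"))

  perm <- c(3, 1, 2)
  rho_p <- rho[perm, perm]
  tree_p <- cluster_correlation_matrix(rho_p)
  expect_identical(tree$leaf_order, tree_p$leaf_order)
  expect_equal(tree$hclust$height, tree_p$hclust$height)
  expect_identical(cluster_tree_newick(tree), cluster_tree_newick(tree_p))

  expect_error(cluster_correlation_matrix(rho[1, 1, drop = FALSE]), "2 genes")
  na_rho <- rho; na_rho["A", "C"] <- na_rho["C", "A"] <- NA
  expect_warning(cluster_correlation_matrix(na_rho), "imputed")
})

test_that("long-format export mirrors the matrix entries", {
  base <- tibble::tibble(gene = "gA", treatment = "LP",
                         time_h = rep(c(3, 6, 12, 18, 24), each = 3),
                         bio_rep = rep(1:3, 5),
                         rel_expr = seq_len(15) + rnorm(15, 0, 0.01))
  expr <- dplyr::bind_rows(
    base,
    dplyr::mutate(base, gene = "gB", rel_expr = .data$rel_expr * 2),
    dplyr::mutate(base, gene = "gC", rel_expr = rev(.data$rel_expr)))
  m <- within_treatment_matrix(expr, "LP")
  long <- correlation_matrix_long(m)
  expect_equal(nrow(long), 3)
  for (k in seq_len(nrow(long))) {
    expect_equal(long$rho[k], m$rho[long$gene_a[k], long$gene_b[k]])
    expect_equal(long$significant[k], m$mask[long$gene_a[k], long$gene_b[k]])
  }
})
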