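test_that("comparison sets enumerate consecutive-time and between-treatment pairs", {
  d1 <- experiment_design("g1", "hk", c("LP", "LK"), "PBS", c(3, 6, 12, 18, 24))
  c1 <- build_comparison_set(d1)
  expect_equal(nrow(c1), 4 + 4 + 5)
  expect_false(any(duplicated(c1)))
  expect_equal(sum(c1$kind == "consecutive_within_treatment"), 8)
  expect_equal(sum(c1$kind == "between_treatments_same_time"), 5)
  # consecutive pairs use adjacent times; between pairs share the time
  consec <- c1[c1$kind == "consecutive_within_treatment", ]
  expect_true(all(match(consec$b_time, d1$times_h) -
                    match(consec$a_time, d1$times_h) == 1))
  betw <- c1[c1$kind == "between_treatments_same_time", ]
  expect_true(all(betw$a_time == betw$b_time))

  d10 <- default_design()
  expect_equal(nrow(build_comparison_set(d10)), 130)

  d_min <- experiment_design("g1", "hk", "LP", "PBS", c(3, 6))
  expect_equal(nrow(build_comparison_set(d_min)), 1)
})

test_that("star labels follow the caption thresholds with strict boundaries", {
  expect_equal(significance_stars(0.04), "*")
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(c(0.05, 0.01, 0.001)), c("ns", "*", "**"))
  expect_equal(significance_stars(0.2), "ns")
  expect_error(significance_stars(-0.1), "\\[0, 1\\]")
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
})

test_that("Dunn pairwise test matches a hand-computed example and Bonferroni is monotone", {
  # 3 groups, no ties: ranks 1..9
  vals <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  grp <- rep(c("a", "b", "c"), each = 3)
  dn <- dunn_test(vals, grp)
  # mean ranks 2, 5, 8; se = sqrt((9*10/12)*(2/3)) = sqrt(5)
  ab <- dn[dn$group_a == "a" & dn$group_b == "b", ]
  expect_equal(ab$z, (2 - 5) / sqrt(5), tolerance = 1e-12)
  expect_equal(ab$p_raw, 2 * pnorm(-abs(ab$z)), tolerance = 1e-12)
  expect_true(all(dn$p_adj >= dn$p_raw - 1e-15))
  expect_true(all(dn$p_adj <= 1))
  expect_equal(dn$p_adj, pmin(1, dn$p_raw * 3), tolerance = 1e-12)
})

test_that("clearly separated groups are significant in both branches", {
  a <- c(1, 1.1, 0.9)
  b <- c(8, 8.1, 7.9)
  # independent check that the data truly separate: exact permutation test
  expect_equal(permutation_test_oracle(a, b), 2 / 20, tolerance = 1e-12)

  expr <- manual_expression(list(LP = a, LK = b))
  d <- experiment_design("g", "hk", c("LP", "LK"), "PBS", 3)
  cmp <- build_comparison_set(d)
  res_par <- test_group_differences(expr, cmp)
  expect_equal(res_par$branch, "anova_tukey")
  expect_lt(res_par$p, 0.001)

  # same data forced through the non-parametric branch (tiny groups)
  expr2 <- manual_expression(list(LP = a[1:2], LK = b[1:2]))
  expect_warning(res_np <- test_group_differences(expr2, cmp), "n < 3")
  expect_equal(res_np$branch, "kruskal_dunn_bonferroni")

  # non-parametric branch significance with larger separated groups
  set.seed(1)
  a2 <- c(1, 1.1, 0.9, 1.05, 0.95, 1.02, 0.98, 30)  # outlier breaks normality
  b2 <- a2 + 100
  expr3 <- manual_expression(list(LP = a2, LK = b2))
  res3 <- test_group_differences(expr3, cmp)
  expect_equal(res3$branch, "kruskal_dunn_bonferroni")
  expect_lt(res3$p, 0.05)
})

test_that("identical groups yield non-significant results", {
  set.seed(7)
  v <- rnorm(3, 1, 0.05)
  expr <- manual_expression(list(LP = v, LK = v))
  d <- experiment_design("g", "hk", c("LP", "LK"), "PBS", 3)
  res <- test_group_differences(expr, build_comparison_set(d))
  expect_equal(res$stars, "ns")
  expect_gt(res$p, 0.9)
})

test_that("branch choice is deterministic and reported per comparison", {
  d <- experiment_design(c("gA", "gB"), "hk", c("LP", "LK"), "PBS", c(3, 6, 12))
  pr <- effect_profiles(d)
  ct <- generate_ct_table(d, pr, seed = 31)
  expr <- compute_relative_expression(ct, "hk", "PBS")
  cmp <- build_comparison_set(d)
  r1 <- test_group_differences(expr, cmp)
  r2 <- test_group_differences(expr, cmp)
  expect_identical(r1, r2)
  expect_true(all(r1$branch %in% c("anova_tukey", "kruskal_dunn_bonferroni")))
  expect_true(all(r1$p >= 0 & r1$p <= 1))
  # stars consistent with p
  expect_identical(r1$stars, significance_stars(r1$p))
})

test_that("consecutive-time contrasts on ddCt data exceed nominal type-I error", {
  # the time-matched control baseline is a shared error term within each
  # group, so adjacent-time null rejections exceed alpha by construction
  r <- simulate_type1_error(n_datasets = 250, seed = 99,
                            kind = "consecutive_within_treatment")
  expect_gt(r$rate, 0.07)
})
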