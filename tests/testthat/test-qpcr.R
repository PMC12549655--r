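ct_row <- function(gene, treatment, time, bio, tech, ct) {
  tibble::tibble(gene = gene, treatment = treatment, time_h = time,
                 bio_rep = bio, tech_rep = tech, ct = ct)
}

test_that("technical replicates collapse to their mean, with a spread warning", {
  tab <- dplyr::bind_rows(
    ct_row("g", "LP", 3, 1, 1, 20.0), ct_row("g", "LP", 3, 1, 2, 20.0),
    ct_row("g", "LP", 3, 2, 1, 20.0), ct_row("g", "LP", 3, 2, 2, 21.0),
    ct_row("g", "LP", 3, 3, 1, 19.5)
  )
  out <- collapse_technical_replicates(tab)
  expect_equal(out$ct[out$bio_rep == 1], 20.0)
  expect_equal(out$ct[out$bio_rep == 2], 20.5)
  expect_equal(out$ct[out$bio_rep == 3], 19.5)  # single replicate passthrough

  noisy <- dplyr::bind_rows(ct_row("g", "LP", 3, 1, 1, 20.0),
                            ct_row("g", "LP", 3, 1, 2, 21.5))
  expect_warning(collapse_technical_replicates(noisy), "spread")
})

test_that("ddCt arithmetic matches the hand-computed example", {
  # sample dCt = 20 - 15 = 5; control dCt mean = 7 -> ddCt = -2 -> 2^2 = 4
  tab <- dplyr::bind_rows(
    ct_row("g", "LP", 3, 1, 1, 20), ct_row("hk", "LP", 3, 1, 1, 15),
    ct_row("g", "PBS", 3, 1, 1, 22), ct_row("hk", "PBS", 3, 1, 1, 15),
    ct_row("g", "PBS", 3, 2, 1, 22), ct_row("hk", "PBS", 3, 2, 1, 15)
  )
  expr <- compute_relative_expression(tab, "hk", "PBS")
  expect_equal(expr$rel_expr[expr$treatment == "LP"], 4.0)
  # control replicates identical to their own mean -> exactly 1
  expect_equal(expr$rel_expr[expr$treatment == "PBS"], c(1, 1))
})

test_that("missing housekeeping or control cells raise structured errors", {
  no_hk <- dplyr::bind_rows(ct_row("g", "LP", 3, 1, 1, 20),
                            ct_row("g", "PBS", 3, 1, 1, 21),
                            ct_row("hk", "PBS", 3, 1, 1, 15))
  expect_error(compute_relative_expression(no_hk, "hk", "PBS"),
               "no housekeeping Ct")
  no_ctrl <- dplyr::bind_rows(ct_row("g", "LP", 3, 1, 1, 20),
                              ct_row("hk", "LP", 3, 1, 1, 15),
                              ct_row("g", "LP", 6, 1, 1, 20),
                              ct_row("hk", "LP", 6, 1, 1, 15),
                              ct_row("g", "PBS", 3, 1, 1, 21),
                              ct_row("hk", "PBS", 3, 1, 1, 15))
  expect_error(compute_relative_expression(no_ctrl, "hk", "PBS"),
               "no control-arm cell")
})

test_that("relative expression is invariant to per-sample Ct shifts", {
  d <- experiment_design(c("gA", "gB"), "hk", "LP", "PBS", c(3, 6))
  pr <- effect_profiles(d, noise_sd = 0.2, tech_sd = 0.1)
  ct <- generate_ct_table(d, pr, seed = 21)
  expr0 <- compute_relative_expression(ct, "hk", "PBS")
  # add an arbitrary constant to every Ct of each sample (gene + housekeeping)
  shifted <- ct |>
    dplyr::group_by(.data$treatment, .data$time_h, .data$bio_rep) |>
    dplyr::mutate(ct = .data$ct + 3.7 * dplyr::cur_group_id()) |>
    dplyr::ungroup()
  expr1 <- compute_relative_expression(shifted, "hk", "PBS")
  expect_equal(expr1$rel_expr, expr0$rel_expr, tolerance = 1e-9)
})

test_that("control-arm mean relative expression is 1 on noise-free data", {
  d <- default_design()
  pr <- effect_profiles(d, noise_sd = 0, tech_sd = 0)
  ct <- generate_ct_table(d, pr, seed = 2)
  expr <- compute_relative_expression(ct, d$housekeeping_gene, d$control_label)
  ctrl_means <- expr |>
    dplyr::filter(.data$treatment == "PBS") |>
    dplyr::group_by(.data$gene, .data$time_h) |>
    dplyr::summarise(m = mean(.data$rel_expr), .groups = "drop")
  expect_equal(ctrl_means$m, rep(1, nrow(ctrl_means)), tolerance = 1e-9)
})

test_that("fold-change bands follow the reporting scheme, boundaries included", {
  expect_equal(classify_fold_change(3.775), "strong_up")
  expect_equal(classify_fold_change(0.532), "mild_down")
  expect_equal(classify_fold_change(1.0), "no_change")
  expect_equal(
    classify_fold_change(c(0.25, 0.4999, 0.5, 0.999, 1.001, 2, 2.001, 39.5)),
    c("strong_down", "strong_down", "mild_down", "mild_down",
      "mild_up", "mild_up", "strong_up", "strong_up"))
  expect_error(classify_fold_change(0), "finite and > 0")
  expect_error(classify_fold_change(-2), "finite and > 0")
  expect_error(classify_fold_change(Inf), "finite and > 0")
})

test_that("expression summaries report mean, n-1 SD, median and the mean's band", {
  expr <- tibble::tibble(gene = "g", treatment = "LP", time_h = 3,
                         bio_rep = 1:3, rel_expr = c(2, 4, 6))
  s <- summarize_expression(expr)
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 2)
  expect_equal(s$median, 4)
  expect_equal(s$band, "strong_up")

  flat <- tibble::tibble(gene = "g", treatment = "LP", time_h = 3,
                         bio_rep = 1:3, rel_expr = c(1, 1, 1))
  sf <- summarize_expression(flat)
  expect_equal(sf$mean, 1)
  expect_equal(sf$sd, 0)
  expect_equal(sf$band, "no_change")
})

test_that("Ct CSV round trip preserves the table", {
  d <- experiment_design("g", "hk", "LP", "PBS", 3)
  ct <- generate_ct_table(d, effect_profiles(d), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_csv(ct, path)
  back <- read_ct_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ct), tolerance = 1e-12)
  expect_error(read_ct_csv(withr::local_tempfile(fileext = ".csv")))
})
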