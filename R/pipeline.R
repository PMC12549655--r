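#' Configure an end-to-end pipeline run
#'
#' Collects every tunable of the analysis in one validated object: the
#' design and data sources (paths to deposited CSV/FASTA files, or the
#' synthetic generators when paths are NULL), the seed, and all reporting
#' thresholds (significance level, gate level, fold-change band edges,
#' correlation strength breaks, clustering linkage, residue class map).
#' The published reporting thresholds are the defaults, so sensitivity
#' analyses are one-argument changes.
#'
#' @param output_dir Directory for stage outputs (created if needed).
#' @param seed Integer seed recorded in the report and used for every
#'   synthetic stage.
#' @param design An [experiment_design()] (default [default_design()]).
#' @param profiles An [effect_profiles()] for synthetic Ct generation;
#'   default is the null profile over `design`.
#' @param ct_csv Optional path to a deposited raw Ct CSV; overrides the
#'   synthetic generator.
#' @param health_csv Optional path to a deposited health-observation CSV.
#' @param health_prof A [health_profile()] (or named list per group) for the
#'   synthetic health stage (default [health_profile_healthy()]).
#' @param alignment_fastas Character vector of aligned-FASTA paths; when
#'   NULL one synthetic pair is generated.
#' @param alpha Significance level for stars and masks (default 0.05).
#' @param gate_alpha Level of the normality/homogeneity gates (default 0.05).
#' @param fc_edges Fold-change strong-band edges (default `c(0.5, 2)`).
#' @param rho_breaks Correlation strength breaks (default `c(0.3, 0.5, 0.7)`).
#' @param linkage Clustering linkage (default `"average"`).
#' @param classes Residue class map or path to a YAML class map.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed = 1L,
                            design = default_design(),
                            profiles = NULL,
                            ct_csv = NULL, health_csv = NULL,
                            health_prof = health_profile_healthy(),
                            alignment_fastas = NULL,
                            alpha = 0.05, gate_alpha = 0.05,
                            fc_edges = c(0.5, 2),
                            rho_breaks = c(0.3, 0.5, 0.7),
                            linkage = "average",
                            classes = default_residue_classes()) {
  stopifnot(inherits(design, "experiment_design"))
  if (is.null(profiles)) profiles <- effect_profiles(design)
  if (is.character(classes) && length(classes) == 1 && is.null(names(classes))) {
    classes <- read_residue_classes(classes)  # a path to a YAML class map
  }
  classes <- validate_residue_classes(classes)
  stopifnot(alpha > 0, alpha < 1, gate_alpha > 0, gate_alpha < 1,
            !is.unsorted(fc_edges, strictly = TRUE),
            !is.unsorted(rho_breaks, strictly = TRUE))
  structure(
    list(output_dir = output_dir, seed = as.integer(seed), design = design,
         profiles = profiles, ct_csv = ct_csv, health_csv = health_csv,
         health_prof = health_prof, alignment_fastas = alignment_fastas,
         alpha = alpha, gate_alpha = gate_alpha, fc_edges = fc_edges,
         rho_breaks = rho_breaks, linkage = linkage, classes = classes),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (deposited files or synthetic
#' generation), health-index scoring and survival, ddCt relative expression
#' with summaries and fold-change bands, the gated comparison tests,
#' cross- and within-treatment Spearman correlation, hierarchical
#' clustering, and consensus derivation for each alignment. Every stage
#' writes a CSV/TSV/Newick/FASTA file under `config$output_dir`, and a
#' `report.json` records the seed, thresholds and stage file names.
#' Re-running with the same config and seed reproduces byte-identical
#' outputs. A stage failure aborts with an error naming the stage; files
#' already written are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(config$output_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  design <- config$design
  files <- character(0)
  results <- list()

  # -- simulate / load -------------------------------------------------------
  ct <- stage("ct_input", {
    if (!is.null(config$ct_csv)) read_ct_csv(config$ct_csv)
    else generate_ct_table(design, config$profiles, seed = config$seed)
  })
  write_ct_csv(ct, out_path("ct_table.csv")); files <- c(files, "ct_table.csv")
  results$ct <- ct

  health <- stage("health_input", {
    if (!is.null(config$health_csv)) {
      readr::read_csv(config$health_csv, show_col_types = FALSE, progress = FALSE)
    } else {
      generate_health_observations(design, config$health_prof,
                                   seed = config$seed + 1L)
    }
  })
  readr::write_csv(health, out_path("health_observations.csv"))
  files <- c(files, "health_observations.csv")

  # -- health ----------------------------------------------------------------
  results$health_summary <- stage("health", aggregate_health(health))
  results$survival <- stage("health", survival_fraction(health))
  readr::write_csv(results$health_summary, out_path("health_summary.csv"))
  readr::write_csv(results$survival, out_path("survival.csv"))
  files <- c(files, "health_summary.csv", "survival.csv")

  # -- expression ------------------------------------------------------------
  expr <- stage("express", compute_relative_expression(
    ct, design$housekeeping_gene, design$control_label))
  summ <- stage("express", summarize_expression(expr))
  summ$band <- classify_fold_change(summ$mean, edges = config$fc_edges)
  readr::write_csv(expr, out_path("expression.csv"))
  readr::write_csv(summ, out_path("expression_summary.csv"))
  files <- c(files, "expression.csv", "expression_summary.csv")
  results$expression <- expr
  results$summary <- summ

  # -- comparison tests ------------------------------------------------------
  results$tests <- stage("stats", {
    comparisons <- build_comparison_set(design)
    test_group_differences(expr, comparisons, alpha = config$alpha,
                           gate_alpha = config$gate_alpha)
  })
  readr::write_csv(results$tests, out_path("comparison_tests.csv"))
  files <- c(files, "comparison_tests.csv")

  # -- correlation + clustering ---------------------------------------------
  results$cross_correlation <- stage("correlate", {
    if (length(design$treatments) >= 2) {
      pairs <- utils::combn(design$treatments, 2)
      dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
        dplyr::bind_rows(lapply(design$target_genes, function(g) {
          cross_treatment_correlation(expr, g, pairs[1, j], pairs[2, j],
                                      alpha = config$alpha)
        }))
      }))
    } else {
      tibble::tibble()
    }
  })
  if (nrow(results$cross_correlation) > 0) {
    results$cross_correlation$category <- classify_correlation_strength(
      results$cross_correlation$rho, results$cross_correlation$p,
      alpha = config$alpha, breaks = config$rho_breaks)
    readr::write_csv(results$cross_correlation, out_path("cross_treatment_correlation.csv"))
    files <- c(files, "cross_treatment_correlation.csv")
  }

  results$matrices <- stage("correlate", {
    lapply(stats::setNames(design$treatments, design$treatments), function(tr) {
      within_treatment_matrix(expr, tr, alpha = config$alpha)
    })
  })
  results$trees <- stage("cluster", {
    lapply(results$matrices, cluster_correlation_matrix, linkage = config$linkage)
  })
  for (tr in names(results$matrices)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", tr)
    long <- correlation_matrix_long(results$matrices[[tr]])
    long$category <- classify_correlation_strength(
      long$rho, long$p, alpha = config$alpha, breaks = config$rho_breaks)
    f_csv <- sprintf("correlation_%s.csv", safe)
    f_nwk <- sprintf("tree_%s.nwk", safe)
    readr::write_csv(long, out_path(f_csv))
    writeLines(cluster_tree_newick(results$trees[[tr]]), out_path(f_nwk))
    files <- c(files, f_csv, f_nwk)
  }

  # -- consensus --------------------------------------------------------------
  results$consensus <- stage("consensus", {
    pairs <- if (!is.null(config$alignment_fastas)) {
      lapply(config$alignment_fastas, read_aligned_pair)
    } else {
      list(generate_alignment_pair(200, seed = config$seed + 2L,
                                   classes = config$classes))
    }
    lapply(pairs, function(p) {
      cons <- derive_consensus(p, classes = config$classes)
      list(pair = p, consensus = cons, metrics = alignment_metrics(p))
    })
  })
  for (i in seq_along(results$consensus)) {
    f_fa <- sprintf("consensus_%02d.fasta", i)
    f_tsv <- sprintf("consensus_%02d_columns.tsv", i)
    write_consensus(results$consensus[[i]]$consensus, out_path(f_fa),
                    out_path(f_tsv))
    files <- c(files, f_fa, f_tsv)
  }

  # -- report ------------------------------------------------------------------
  report <- list(
    seed = config$seed,
    alpha = config$alpha,
    gate_alpha = config$gate_alpha,
    fc_edges = config$fc_edges,
    rho_breaks = config$rho_breaks,
    linkage = config$linkage,
    design = list(
      target_genes = design$target_genes,
      housekeeping_gene = design$housekeeping_gene,
      treatments = design$treatments,
      control_label = design$control_label,
      times_h = design$times_h,
      n_bio = design$n_bio,
      n_tech = design$n_tech
    ),
    n_expression_rows = nrow(expr),
    n_comparisons = nrow(results$tests),
    files = files
  )
  jsonlite::write_json(report, out_path("report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$report <- report
  invisible(results)
}
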