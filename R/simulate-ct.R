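#' Simulate a raw Ct table for a screening design
#'
#' Generates one qPCR measurement per gene x treatment x time x biological
#' replicate x technical replicate, housekeeping gene included. Target Ct is
#' `baseline_ct[gene] - log2(fc) + bio + tech` and housekeeping Ct is
#' `hk_ct + bio + tech`, where `bio ~ N(0, noise_sd)` is drawn once per
#' gene x biological sample and `tech ~ N(0, tech_sd)` once per well. With
#' both SDs zero the downstream ddCt pipeline recovers the injected fold
#' changes exactly.
#'
#' @param design An [experiment_design()].
#' @param profiles An [effect_profiles()] covering every cell of the design.
#' @param seed Integer seed; identical seeds yield identical tables.
#'
#' @return A tibble with columns `gene`, `treatment`, `time_h`, `bio_rep`,
#'   `tech_rep`, `ct` (the raw Ct table schema used throughout the package).
#' @export
generate_ct_table <- function(design, profiles, seed) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(profiles, "effect_profiles"))
  arms <- design_arms(design)
  cells <- tidyr::expand_grid(gene = design$target_genes,
                              treatment = arms,
                              time_h = design$times_h)
  fc_tab <- dplyr::left_join(cells, profiles$fc,
                             by = c("gene", "treatment", "time_h"))
  miss <- fc_tab[is.na(fc_tab$fc), ]
  if (nrow(miss) > 0) {
    stop(sprintf("effect profile missing for cell gene=%s treatment=%s time_h=%s",
                 miss$gene[1], miss$treatment[1], miss$time_h[1]), call. = FALSE)
  }

  set.seed(as.integer(seed))

  genes_all <- c(design$target_genes, design$housekeeping_gene)
  grid <- tidyr::expand_grid(gene = genes_all,
                             treatment = arms,
                             time_h = design$times_h,
                             bio_rep = seq_len(design$n_bio),
                             tech_rep = seq_len(design$n_tech))

  mu <- ifelse(grid$gene == design$housekeeping_gene,
               profiles$hk_ct,
               profiles$baseline_ct[grid$gene] -
                 log2(fc_tab$fc[match(paste(grid$gene, grid$treatment, grid$time_h),
                                      paste(fc_tab$gene, fc_tab$treatment, fc_tab$time_h))]))

  # one biological draw per gene x arm x time x bio sample, shared by wells
  bio_key <- paste(grid$gene, grid$treatment, grid$time_h, grid$bio_rep, sep = "\r")
  uk <- unique(bio_key)
  bio_noise <- stats::setNames(stats::rnorm(length(uk), 0, profiles$noise_sd), uk)
  tech_noise <- stats::rnorm(nrow(grid), 0, profiles$tech_sd)

  grid$ct <- as.numeric(mu + bio_noise[bio_key] + tech_noise)
  tibble::as_tibble(grid)
}

#' Read / write raw Ct tables
#'
#' `read_ct_csv()` loads a long-format Ct table (the schema deposited with
#' the study: `gene,treatment,time_h,bio_rep,tech_rep,ct`) and validates it;
#' `write_ct_csv()` writes one.
#'
#' @param path CSV file path.
#' @return `read_ct_csv()` returns the validated tibble.
#' @export
read_ct_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_ct_table(tab)
}

#' @rdname read_ct_csv
#' @param table A Ct table.
#' @export
write_ct_csv <- function(table, path) {
  readr::write_csv(validate_ct_table(table), path)
  invisible(path)
}

validate_ct_table <- function(table) {
  need <- c("gene", "treatment", "time_h", "bio_rep", "ct")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    stop("Ct table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(table$ct)) || any(table$ct <= 0)) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  tibble::as_tibble(table)
}
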