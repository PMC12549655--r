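#' Define a qRT-PCR screening design
#'
#' Describes the factorial layout of a time-course expression screen:
#' which target genes are assayed, the housekeeping (reference) gene,
#' the treatment arms (including the vehicle control), the sampling
#' times and the replicate structure.
#'
#' @param target_genes Character vector of target gene identifiers.
#' @param housekeeping_gene Single reference gene identifier; must not be
#'   among `target_genes`.
#' @param treatments Character vector of treatment labels (the arms that
#'   receive an active inoculum).
#' @param control_label Label of the vehicle control arm (e.g. `"PBS"`).
#' @param times_h Strictly increasing numeric vector of sampling times in
#'   hours post-treatment.
#' @param n_bio Number of biological replicates per arm and time (>= 1).
#' @param n_tech Number of technical (qPCR well) replicates per biological
#'   sample (>= 1).
#'
#' @return An object of class `experiment_design`.
#' @seealso [default_design()] for the ten-gene probiotic screen layout.
#' @export
experiment_design <- function(target_genes, housekeeping_gene, treatments,
                              control_label, times_h, n_bio = 3L, n_tech = 2L) {
  stopifnot(is.character(target_genes), length(target_genes) >= 1,
            is.character(housekeeping_gene), length(housekeeping_gene) == 1,
            is.character(treatments), length(treatments) >= 1,
            is.character(control_label), length(control_label) == 1,
            is.numeric(times_h), length(times_h) >= 1)
  if (housekeeping_gene %in% target_genes) {
    stop("housekeeping_gene must not be one of the target genes", call. = FALSE)
  }
  if (anyDuplicated(target_genes)) {
    stop("target_genes must be unique", call. = FALSE)
  }
  if (is.unsorted(times_h, strictly = TRUE)) {
    stop("times_h must be strictly increasing", call. = FALSE)
  }
  if (control_label %in% treatments) {
    stop("control_label names the control arm and must not appear in `treatments`",
         call. = FALSE)
  }
  n_bio <- as.integer(n_bio)
  n_tech <- as.integer(n_tech)
  if (n_bio < 1L || n_tech < 1L) {
    stop("n_bio and n_tech must both be >= 1", call. = FALSE)
  }
  structure(
    list(target_genes = target_genes,
         housekeeping_gene = housekeeping_gene,
         treatments = treatments,
         control_label = control_label,
         times_h = as.numeric(times_h),
         n_bio = n_bio,
         n_tech = n_tech),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>\n")
  cat("  target genes :", length(x$target_genes),
      paste0("(", paste(utils::head(x$target_genes, 4), collapse = ", "),
             if (length(x$target_genes) > 4) ", ..." else "", ")"), "\n")
  cat("  housekeeping :", x$housekeeping_gene, "\n")
  cat("  treatments   :", paste(x$treatments, collapse = ", "),
      "| control:", x$control_label, "\n")
  cat("  times (h)    :", paste(x$times_h, collapse = ", "), "\n")
  cat("  replicates   :", x$n_bio, "biological x", x$n_tech, "technical\n")
  invisible(x)
}

#' All treatment arms of a design, control included
#'
#' @param design An [experiment_design()].
#' @return Character vector: the active treatments followed by the control.
#' @export
design_arms <- function(design) {
  c(design$treatments, design$control_label)
}

#' The ten-gene probiotic immunomodulation screen layout
#'
#' The default design mirrors the screen this package was written for:
#' ten innate-immunity genes of *Galleria mellonella* (Toll/IMD pathway
#' regulators, antimicrobial peptides, an NADPH oxidase and cellular
#' effectors), the *eEF1alpha1* housekeeping gene, two probiotic arms
#' (LP = *Lactiplantibacillus plantarum*, LK = *Lentilactobacillus kefiri*)
#' against a PBS control, five sampling times (3, 6, 12, 18, 24 h) and
#' 3 biological x 2 technical replicates. Every dimension is configurable
#' through [experiment_design()].
#'
#' @return An `experiment_design`.
#' @export
default_design <- function() {
  experiment_design(
    target_genes = c("Dorsal", "Rel", "cad", "18w", "spz4",
                     "gallerimycin", "gloverin", "NADPH oxidase 4",
                     "Hem", "IMPI"),
    housekeeping_gene = "eEF1alpha1",
    treatments = c("LP", "LK"),
    control_label = "PBS",
    times_h = c(3, 6, 12, 18, 24),
    n_bio = 3L,
    n_tech = 2L
  )
}

#' Effect profiles: the ground truth injected into synthetic Ct tables
#'
#' An effect-profile set fixes, for every (gene, treatment, time) cell of a
#' design, the target fold change relative to the control arm, plus the
#' baseline Ct level of each gene, the housekeeping Ct, and the Ct-scale
#' noise standard deviations. Fold changes in the control arm are identically
#' 1 by construction.
#'
#' Noise is placed on Ct (additive Gaussian) rather than on linear
#' expression because qPCR measurement error is approximately log-scale and
#' the ddCt algebra is linear in Ct. Biological and technical noise are
#' drawn independently: `noise_sd` acts once per biological sample and
#' `tech_sd` once per well.
#'
#' @param design An [experiment_design()].
#' @param fc Either a single positive number applied to every
#'   gene x treatment x time cell (default 1 = null profile), or a data
#'   frame with columns `gene`, `treatment`, `time_h`, `fc` covering every
#'   cell of the design's active treatments. Control-arm fold changes are
#'   always 1 and must not be supplied.
#' @param baseline_ct Named numeric vector of per-gene baseline Ct values
#'   (control-arm expected Ct). By default evenly spread over 24--30 cycles.
#' @param hk_ct Housekeeping-gene Ct level (default 18).
#' @param noise_sd Biological Ct noise SD in cycles (default 0.15).
#' @param tech_sd Technical Ct noise SD in cycles (default 0.10).
#'
#' @return An object of class `effect_profiles` with a complete `fc` table.
#' @export
effect_profiles <- function(design, fc = 1, baseline_ct = NULL, hk_ct = 18,
                            noise_sd = 0.15, tech_sd = 0.10) {
  stopifnot(inherits(design, "experiment_design"))
  if (noise_sd < 0 || tech_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  full <- tidyr::expand_grid(
    gene = design$target_genes,
    treatment = design_arms(design),
    time_h = design$times_h
  )
  if (is.numeric(fc) && length(fc) == 1) {
    if (!is.finite(fc) || fc <= 0) stop("fc must be a positive number", call. = FALSE)
    full$fc <- ifelse(full$treatment == design$control_label, 1, fc)
  } else if (is.data.frame(fc)) {
    need <- c("gene", "treatment", "time_h", "fc")
    if (!all(need %in% names(fc))) {
      stop("fc data frame needs columns gene, treatment, time_h, fc", call. = FALSE)
    }
    if (any(fc$treatment == design$control_label & fc$fc != 1)) {
      stop("control-arm fold changes are fixed at 1 and cannot be overridden",
           call. = FALSE)
    }
    if (any(!is.finite(fc$fc) | fc$fc <= 0)) {
      stop("all fold changes must be finite and > 0", call. = FALSE)
    }
    full <- dplyr::left_join(full, fc[need], by = c("gene", "treatment", "time_h"))
    full$fc[full$treatment == design$control_label] <- 1
    miss <- full[is.na(full$fc), ]
    if (nrow(miss) > 0) {
      stop(sprintf("missing fold-change for %d cell(s), first: gene=%s treatment=%s time_h=%s",
                   nrow(miss), miss$gene[1], miss$treatment[1], miss$time_h[1]),
           call. = FALSE)
    }
  } else {
    stop("fc must be a positive scalar or a data frame", call. = FALSE)
  }
  if (is.null(baseline_ct)) {
    k <- length(design$target_genes)
    baseline_ct <- stats::setNames(seq(24, 30, length.out = max(k, 2))[seq_len(k)],
                                   design$target_genes)
  }
  if (!all(design$target_genes %in% names(baseline_ct))) {
    stop("baseline_ct must name every target gene", call. = FALSE)
  }
  structure(
    list(fc = tibble::as_tibble(full),
         baseline_ct = baseline_ct,
         hk_ct = hk_ct,
         noise_sd = noise_sd,
         tech_sd = tech_sd),
    class = "effect_profiles"
  )
}

#' Set injected fold changes for specific cells
#'
#' Convenience editor for an [effect_profiles()] object: assigns `fc` to the
#' given gene/treatment at one or more time points (recycled as usual).
#'
#' @param profiles An `effect_profiles` object.
#' @param gene,treatment Cell coordinates (single gene, single treatment).
#' @param time_h Time point(s) to set.
#' @param fc Positive fold change(s), recycled over `time_h`.
#' @return The modified `effect_profiles`.
#' @export
set_fc <- function(profiles, gene, treatment, time_h, fc) {
  stopifnot(inherits(profiles, "effect_profiles"))
  if (any(!is.finite(fc) | fc <= 0)) stop("fc must be positive", call. = FALSE)
  fc <- rep_len(fc, length(time_h))
  for (i in seq_along(time_h)) {
    sel <- profiles$fc$gene == gene &
      profiles$fc$treatment == treatment &
      profiles$fc$time_h == time_h[i]
    if (!any(sel)) {
      stop(sprintf("no profile cell gene=%s treatment=%s time_h=%s",
                   gene, treatment, time_h[i]), call. = FALSE)
    }
    profiles$fc$fc[sel] <- fc[i]
  }
  profiles
}
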