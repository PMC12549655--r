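#' Collapse technical qPCR replicates
#'
#' Averages technical (well) replicates so that one Ct remains per
#' gene x treatment x time x biological sample. Wells of the same sample
#' whose Ct values span more than `warn_threshold` cycles trigger a warning
#' (a common QC flag for pipetting or amplification problems).
#'
#' @param table A raw Ct table (`gene,treatment,time_h,bio_rep,tech_rep,ct`).
#' @param warn_threshold Maximum tolerated within-sample Ct spread in cycles
#'   (default 1).
#' @return A Ct table with one row per biological sample (no `tech_rep`).
#' @export
collapse_technical_replicates <- function(table, warn_threshold = 1) {
  table <- validate_ct_table(table)
  out <- table |>
    dplyr::group_by(.data$gene, .data$treatment, .data$time_h, .data$bio_rep) |>
    dplyr::summarise(spread = max(.data$ct) - min(.data$ct),
                     ct = mean(.data$ct), .groups = "drop")
  n_bad <- sum(out$spread > warn_threshold)
  if (n_bad > 0) {
    warning(sprintf("%d sample(s) with technical-replicate Ct spread > %g cycles",
                    n_bad, warn_threshold), call. = FALSE)
  }
  out$spread <- NULL
  out
}

#' Relative expression by the ddCt method
#'
#' Computes per-biological-replicate relative expression
#' \eqn{2^{-\Delta\Delta Ct}}: each target Ct is first normalised against
#' the housekeeping gene measured in the same sample
#' (\eqn{\Delta Ct = Ct_{target} - Ct_{HK}}), then referenced to the mean
#' \eqn{\Delta Ct} of the control-arm replicates of the same gene at the
#' same time point (\eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta
#' Ct}_{control}}). The control baseline is time-matched, so control-arm
#' relative expression has geometric mean 1 per gene and time by
#' construction (arithmetic mean 1 on noise-free data).
#'
#' Technical replicates must be collapsed first (see
#' [collapse_technical_replicates()]); if a `tech_rep` column is present the
#' collapse is applied automatically.
#'
#' @param table A Ct table.
#' @param housekeeping Housekeeping gene identifier present in every sample.
#' @param control_label Label of the control arm.
#' @return A tibble `gene,treatment,time_h,bio_rep,rel_expr` for every
#'   target gene (housekeeping rows are consumed, not returned).
#' @export
compute_relative_expression <- function(table, housekeeping, control_label) {
  if ("tech_rep" %in% names(table)) {
    table <- collapse_technical_replicates(table)
  } else {
    table <- validate_ct_table(table)
  }
  if (!housekeeping %in% table$gene) {
    stop(sprintf("housekeeping gene '%s' absent from table", housekeeping),
         call. = FALSE)
  }
  if (!control_label %in% table$treatment) {
    stop(sprintf("control arm '%s' absent from table", control_label),
         call. = FALSE)
  }
  hk <- table |>
    dplyr::filter(.data$gene == housekeeping) |>
    dplyr::select("treatment", "time_h", "bio_rep", hk_ct = "ct")
  targets <- dplyr::filter(table, .data$gene != housekeeping)
  joined <- dplyr::left_join(targets, hk, by = c("treatment", "time_h", "bio_rep"))
  if (any(is.na(joined$hk_ct))) {
    bad <- joined[is.na(joined$hk_ct), ][1, ]
    stop(sprintf("no housekeeping Ct for sample treatment=%s time_h=%s bio_rep=%s",
                 bad$treatment, bad$time_h, bad$bio_rep), call. = FALSE)
  }
  joined$dct <- joined$ct - joined$hk_ct

  ctrl <- joined |>
    dplyr::filter(.data$treatment == control_label) |>
    dplyr::group_by(.data$gene, .data$time_h) |>
    dplyr::summarise(ctrl_dct = mean(.data$dct), .groups = "drop")
  joined <- dplyr::left_join(joined, ctrl, by = c("gene", "time_h"))
  if (any(is.na(joined$ctrl_dct))) {
    bad <- joined[is.na(joined$ctrl_dct), ][1, ]
    stop(sprintf("no control-arm cell for gene=%s time_h=%s",
                 bad$gene, bad$time_h), call. = FALSE)
  }
  joined |>
    dplyr::mutate(rel_expr = 2^(-(.data$dct - .data$ctrl_dct))) |>
    dplyr::select("gene", "treatment", "time_h", "bio_rep", "rel_expr")
}

#' Fold-change bands
#'
#' Classifies a positive fold change into the five reporting bands:
#' strong downregulation (FC < 0.5), mild downregulation (0.5 <= FC < 1),
#' no change (FC = 1), mild upregulation (1 < FC <= 2) and strong
#' upregulation (FC > 2). FC exactly 1 sits in neither printed band and is
#' labelled `no_change`.
#'
#' @param fc Positive finite fold change(s).
#' @param edges Length-2 vector: the strong-band edges `c(lower, upper)`
#'   (defaults `c(0.5, 2)`, the reported scheme).
#' @return Character vector of band labels.
#' @export
classify_fold_change <- function(fc, edges = c(0.5, 2)) {
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    stop("fold changes must be finite and > 0", call. = FALSE)
  }
  stopifnot(length(edges) == 2, edges[1] < 1, edges[2] > 1)
  dplyr::case_when(
    fc > edges[2] ~ "strong_up",
    fc > 1 ~ "mild_up",
    fc == 1 ~ "no_change",
    fc >= edges[1] ~ "mild_down",
    TRUE ~ "strong_down"
  )
}

#' Summarise relative expression per gene, treatment and time
#'
#' Reports the arithmetic mean, sample SD (n - 1 denominator) and median of
#' the per-replicate \eqn{2^{-\Delta\Delta Ct}} values, plus the fold-change
#' band of the mean. Cells with a single replicate get `NA` SD.
#'
#' @param expr An expression table from [compute_relative_expression()].
#' @return A tibble `gene,treatment,time_h,n,mean,sd,median,band`.
#' @export
summarize_expression <- function(expr) {
  expr |>
    dplyr::group_by(.data$gene, .data$treatment, .data$time_h) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$rel_expr),
      sd = stats::sd(.data$rel_expr),
      median = stats::median(.data$rel_expr),
      .groups = "drop"
    ) |>
    dplyr::mutate(band = classify_fold_change(.data$mean))
}
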