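#' Spearman rank correlation with a small-sample exact p-value
#'
#' Computes Spearman's rho (average ranks for ties) with a two-sided
#' p-value: for n >= 10 the usual t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom; for
#' n < 10 an exact permutation test enumerating all n! orderings of one
#' margin (tie structure respected, since ranks are permuted as observed).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A list with `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t_approximation"
  } else {
    rx <- rank(x)
    ry <- rank(y)
    perms <- all_permutations(n)
    # rho is monotone in sum(rx * ry_perm); permutation mean/sd of ranks fixed
    stat_obs <- sum(rx * ry)
    stats_all <- as.vector(rx %*% matrix(ry[perms], nrow = n))
    centre <- n * mean(rx) * mean(ry)
    p <- mean(abs(stats_all - centre) >= abs(stat_obs - centre) - 1e-9)
    method <- "exact_permutation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

# all permutations of 1..n as an n x n! integer matrix (n <= 9), cached
.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  if (n > 9) stop("permutation enumeration limited to n <= 9", call. = FALSE)
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 1L
  for (pos in seq_len(n)) {
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      out[, col] <- append(v, n, after = pos - 1L)
      col <- col + 1L
    }
  }
  .perm_cache[[key]] <- out
  out
}

#' Correlation strength categories
#'
#' Maps a Spearman coefficient to the reporting categories used for the
#' cross-treatment similarity table: none (|rho| < 0.3), weak
#' (0.3 <= |rho| < 0.5), moderate (0.5 <= |rho| < 0.7), strong
#' (|rho| >= 0.7). Coefficients whose p-value is not below `alpha` are
#' reported as `none` regardless of magnitude (the sign is carried by rho
#' itself, not the category).
#'
#' @param rho Correlation coefficient(s) in \[-1, 1\].
#' @param p Two-sided p-value(s).
#' @param alpha Significance threshold (default 0.05).
#' @param breaks Strictly increasing |rho| cut points for the
#'   weak/moderate/strong bands (default `c(0.3, 0.5, 0.7)`).
#' @return Character vector over none/weak/moderate/strong.
#' @export
classify_correlation_strength <- function(rho, p, alpha = 0.05,
                                          breaks = c(0.3, 0.5, 0.7)) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE)) {
    stop("rho must lie in [-1, 1]", call. = FALSE)
  }
  stopifnot(length(breaks) == 3, !is.unsorted(breaks, strictly = TRUE))
  a <- abs(rho)
  dplyr::case_when(
    is.na(rho) | is.na(p) ~ NA_character_,
    p >= alpha ~ "none",
    a >= breaks[3] ~ "strong",
    a >= breaks[2] ~ "moderate",
    a >= breaks[1] ~ "weak",
    TRUE ~ "none"
  )
}

#' Cross-treatment temporal correlation of one gene
#'
#' Measures how similar a gene's temporal expression pattern is under two
#' treatments: per-replicate relative expression values are paired by
#' (time, biological replicate) across the two arms and Spearman-correlated,
#' giving n = times x replicates paired observations (15 in the default
#' design).
#'
#' @param expr Expression table.
#' @param gene Gene to correlate.
#' @param treat_a,treat_b The two treatment arms.
#' @param alpha Significance level for the strength category.
#' @return A tibble row: `gene, treat_a, treat_b, n, rho, p, category`.
#' @export
cross_treatment_correlation <- function(expr, gene, treat_a, treat_b,
                                        alpha = 0.05) {
  g <- gene
  a <- expr |>
    dplyr::filter(.data$gene == g, .data$treatment == treat_a) |>
    dplyr::arrange(.data$time_h, .data$bio_rep)
  b <- expr |>
    dplyr::filter(.data$gene == g, .data$treatment == treat_b) |>
    dplyr::arrange(.data$time_h, .data$bio_rep)
  key_a <- paste(a$time_h, a$bio_rep)
  key_b <- paste(b$time_h, b$bio_rep)
  if (!identical(key_a, key_b)) {
    unmatched <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
    stop(sprintf("unmatched replicate structure between %s and %s for gene %s: %s",
                 treat_a, treat_b, g,
                 paste(unmatched, collapse = "; ")), call. = FALSE)
  }
  st <- spearman_test(a$rel_expr, b$rel_expr)
  tibble::tibble(gene = g, treat_a = treat_a, treat_b = treat_b,
                 n = st$n, rho = st$rho, p = st$p,
                 category = classify_correlation_strength(st$rho, st$p, alpha))
}

#' Within-treatment gene x gene correlation matrix
#'
#' All pairwise Spearman correlations between target genes under one
#' treatment, with observations paired by (time, biological replicate), and
#' a significance mask at `alpha`. Gene pairs involving a constant
#' expression vector have undefined rho and are recorded as `NA` (masked
#' not significant), with a warning.
#'
#' @param expr Expression table.
#' @param treatment Treatment arm to analyse.
#' @param alpha Mask level (default 0.05).
#' @return An object of class `correlation_matrix`: list with `treatment`,
#'   `genes`, symmetric matrices `rho` and `p`, logical `mask`
#'   (TRUE iff p < alpha off-diagonal), and `alpha`.
#' @export
within_treatment_matrix <- function(expr, treatment, alpha = 0.05) {
  tr <- treatment
  dat <- expr |>
    dplyr::filter(.data$treatment == tr) |>
    dplyr::arrange(.data$gene, .data$time_h, .data$bio_rep)
  genes <- sort(unique(dat$gene))
  if (length(genes) < 2) stop("need at least 2 genes", call. = FALSE)
  vecs <- lapply(genes, function(g) dat$rel_expr[dat$gene == g])
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1) {
    stop("genes have unequal observation counts under this treatment", call. = FALSE)
  }
  k <- length(genes)
  rho <- matrix(NA_real_, k, k, dimnames = list(genes, genes))
  pmat <- matrix(NA_real_, k, k, dimnames = list(genes, genes))
  diag(rho) <- 1
  diag(pmat) <- 0
  n_undef <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      st <- spearman_test(vecs[[i]], vecs[[j]])
      if (is.na(st$rho)) n_undef <- n_undef + 1L
      rho[i, j] <- rho[j, i] <- st$rho
      pmat[i, j] <- pmat[j, i] <- st$p
    }
  }
  if (n_undef > 0) {
    warning(sprintf("%d gene pair(s) with constant expression: rho undefined (NA)",
                    n_undef), call. = FALSE)
  }
  mask <- !is.na(pmat) & pmat < alpha
  diag(mask) <- FALSE
  structure(list(treatment = tr, genes = genes, rho = rho, p = pmat,
                 mask = mask, alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> treatment=%s, %d genes, %d significant pair(s) at alpha=%g\n",
              x$treatment, length(x$genes), sum(x$mask) / 2, x$alpha))
  invisible(x)
}

#' Hierarchically cluster a gene correlation matrix
#'
#' Agglomerative clustering of genes on the dissimilarity d = 1 - rho
#' (signed: anticorrelated genes are far apart). Genes are ordered
#' lexicographically before clustering so the tree is invariant to the
#' input gene order even under tied merge heights. Missing correlations are
#' imputed as 0 (d = 1) with a warning.
#'
#' @param mat A `correlation_matrix` from [within_treatment_matrix()], or a
#'   plain symmetric correlation matrix with dimnames.
#' @param linkage Agglomeration method for [stats::hclust()]
#'   (default `"average"`; `"complete"` and `"ward.D2"` are sensible
#'   alternatives).
#' @param absolute Use d = 1 - |rho| instead (default FALSE).
#' @return An object of class `cluster_tree`: list with the `hclust` fit,
#'   `leaf_order` (gene labels in dendrogram order), `linkage`, `distance`.
#' @export
cluster_correlation_matrix <- function(mat, linkage = "average",
                                       absolute = FALSE) {
  rho <- if (inherits(mat, "correlation_matrix")) mat$rho else as.matrix(mat)
  if (is.null(rownames(rho))) stop("correlation matrix needs gene dimnames", call. = FALSE)
  if (nrow(rho) < 2) stop("need at least 2 genes to cluster", call. = FALSE)
  ord <- order(rownames(rho))
  rho <- rho[ord, ord]
  if (any(is.na(rho))) {
    warning("missing correlations imputed as 0 for clustering", call. = FALSE)
    rho[is.na(rho)] <- 0
  }
  d <- if (absolute) 1 - abs(rho) else 1 - rho
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(hclust = hc,
                 leaf_order = hc$labels[hc$order],
                 linkage = linkage,
                 distance = if (absolute) "1-|rho|" else "1-rho"),
            class = "cluster_tree")
}

#' Cut a cluster tree into gene modules
#'
#' @param tree A `cluster_tree`.
#' @param k Number of modules.
#' @return Named integer vector of module assignments per gene.
#' @export
cut_modules <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"))
  stats::cutree(tree$hclust, k = k)
}

#' Export a cluster tree as a Newick string
#'
#' @param tree A `cluster_tree`.
#' @return Single Newick string (branch lengths from merge heights).
#' @export
cluster_tree_newick <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  ape::write.tree(ape::as.phylo(tree$hclust))
}

#' Long-format export of a correlation matrix
#'
#' @param mat A `correlation_matrix`.
#' @param alpha Significance level for the strength category column.
#' @return Tibble `gene_a, gene_b, n ... rho, p, category, significant` for
#'   each unordered gene pair.
#' @export
correlation_matrix_long <- function(mat, alpha = mat$alpha) {
  stopifnot(inherits(mat, "correlation_matrix"))
  genes <- mat$genes
  pairs <- utils::combn(genes, 2)
  tibble::tibble(
    treatment = mat$treatment,
    gene_a = pairs[1, ],
    gene_b = pairs[2, ],
    rho = mat$rho[t(pairs)],
    p = mat$p[t(pairs)],
    category = classify_correlation_strength(mat$rho[t(pairs)],
                                             mat$p[t(pairs)], alpha),
    significant = mat$mask[t(pairs)]
  )
}
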