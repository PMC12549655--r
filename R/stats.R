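#' Build the reported comparison set for a design
#'
#' The screen reports two kinds of pairwise contrasts per gene: consecutive
#' time points within each active treatment, and the active treatments
#' against each other at the same time point. For a design with T time
#' points, k active treatments and G genes this yields
#' `G * (k * (T - 1) + choose(k, 2) * T)` comparisons with no duplicates.
#'
#' @param design An [experiment_design()].
#' @return A tibble with columns `gene`, `kind`
#'   (`consecutive_within_treatment` or `between_treatments_same_time`),
#'   `a_treatment`, `a_time`, `b_treatment`, `b_time`.
#' @export
build_comparison_set <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (length(design$times_h) < 2 && length(design$treatments) < 2) {
    stop("need at least 2 time points or 2 treatments to build comparisons",
         call. = FALSE)
  }
  times <- design$times_h
  trts <- design$treatments
  out <- list()
  for (g in design$target_genes) {
    if (length(times) >= 2) {
      for (tr in trts) {
        out[[length(out) + 1]] <- tibble::tibble(
          gene = g, kind = "consecutive_within_treatment",
          a_treatment = tr, a_time = times[-length(times)],
          b_treatment = tr, b_time = times[-1]
        )
      }
    }
    if (length(trts) >= 2) {
      pairs <- utils::combn(trts, 2)
      for (j in seq_len(ncol(pairs))) {
        out[[length(out) + 1]] <- tibble::tibble(
          gene = g, kind = "between_treatments_same_time",
          a_treatment = pairs[1, j], a_time = times,
          b_treatment = pairs[2, j], b_time = times
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Significance star labels
#'
#' @param p Probabilities in \[0, 1\].
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `"ns"` otherwise (strict inequalities: p = 0.05 is `ns`).
#' @export
significance_stars <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' Pairwise rank-sum z tests following a Kruskal-Wallis omnibus test.
#' Observations are ranked over the pooled sample with average ranks for
#' ties; for groups i, j the statistic is
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - C)(1/n_i + 1/n_j)}}
#' with tie correction \eqn{C = \sum_t (t^3 - t) / (12 (N - 1))}. Two-sided
#' normal p-values are Bonferroni-multiplied by the number of pairs and
#' capped at 1.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor).
#' @return A tibble `group_a, group_b, z, p_raw, p_adj` for every pair.
#' @export
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tabulate(groups)
  ties <- table(values)
  tie_c <- sum(ties^3 - ties) / (12 * (N - 1))
  m <- utils::combn(levels(groups), 2)
  res <- vector("list", ncol(m))
  n_pairs <- ncol(m)
  for (j in seq_len(n_pairs)) {
    a <- m[1, j]; b <- m[2, j]
    ia <- which(levels(groups) == a); ib <- which(levels(groups) == b)
    se <- sqrt((N * (N + 1) / 12 - tie_c) * (1 / n[ia] + 1 / n[ib]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    p_raw <- 2 * stats::pnorm(-abs(z))
    res[[j]] <- tibble::tibble(group_a = a, group_b = b, z = z,
                               p_raw = p_raw,
                               p_adj = min(1, p_raw * n_pairs))
  }
  dplyr::bind_rows(res)
}

# Gate helpers ---------------------------------------------------------------

# Shapiro-Wilk per group; constant groups cannot be assessed and count as a
# gate failure (routed to the non-parametric branch with a warning upstream).
shapiro_gate <- function(value_list, alpha) {
  for (v in value_list) {
    if (length(unique(v)) == 1) return(FALSE)
    if (stats::shapiro.test(v)$p.value < alpha) return(FALSE)
  }
  TRUE
}

levene_gate <- function(values, groups, alpha) {
  p <- car::leveneTest(values ~ groups)[["Pr(>F)"]][1]
  is.finite(p) && p >= alpha
}

#' Normality-gated group testing over a comparison set
#'
#' Runs the screen's testing branch on per-replicate relative expression.
#' Comparisons are grouped into *families*, the sets of groups that enter
#' one omnibus test: per gene and treatment, all time points (serving the
#' consecutive-time contrasts); per gene and time, all active treatments
#' (serving the between-treatment contrasts). For each family the branch is
#' gated: if every group passes Shapiro-Wilk normality (p >= `gate_alpha`)
#' and the family passes Levene's homogeneity test (p >= `gate_alpha`), a
#' one-way ANOVA with Tukey HSD pairwise p-values is used; otherwise
#' Kruskal-Wallis with Dunn's pairwise test and Bonferroni correction.
#' Families with fewer than 3 observations in any group are forced onto the
#' non-parametric branch with a warning (the normality gate is powerless
#' there).
#'
#' @param expr Expression table (`gene,treatment,time_h,bio_rep,rel_expr`).
#' @param comparisons A comparison set from [build_comparison_set()].
#' @param alpha Significance level used only for star labelling.
#' @param gate_alpha Level of the Shapiro-Wilk and Levene gates
#'   (default 0.05).
#' @return The comparison tibble with `branch`, `statistic` (omnibus F or
#'   Kruskal-Wallis chi-squared), `p` (Tukey- or Bonferroni-adjusted
#'   pairwise p) and `stars` columns appended.
#' @export
test_group_differences <- function(expr, comparisons, alpha = 0.05,
                                   gate_alpha = 0.05) {
  stopifnot(all(c("gene", "treatment", "time_h", "rel_expr") %in% names(expr)))
  grp_key <- function(treatment, time) paste(treatment, time, sep = "@")

  # family id: one omnibus per (gene, treatment) over times for consecutive
  # contrasts, one per (gene, time) over treatments for between contrasts
  comparisons <- comparisons |>
    dplyr::mutate(family = ifelse(
      .data$kind == "consecutive_within_treatment",
      paste("time", .data$gene, .data$a_treatment, sep = "|"),
      paste("trt", .data$gene, .data$a_time, sep = "|")
    ))

  out <- comparisons
  out$branch <- NA_character_
  out$statistic <- NA_real_
  out$p <- NA_real_

  for (fam in unique(comparisons$family)) {
    idx <- which(comparisons$family == fam)
    fam_rows <- comparisons[idx, ]
    g <- fam_rows$gene[1]
    if (fam_rows$kind[1] == "consecutive_within_treatment") {
      dat <- dplyr::filter(expr, .data$gene == g,
                           .data$treatment == fam_rows$a_treatment[1])
      dat$grp <- grp_key(dat$treatment, dat$time_h)
    } else {
      trts <- unique(c(fam_rows$a_treatment, fam_rows$b_treatment))
      dat <- dplyr::filter(expr, .data$gene == g,
                           .data$time_h == fam_rows$a_time[1],
                           .data$treatment %in% trts)
      dat$grp <- grp_key(dat$treatment, dat$time_h)
    }
    dat$grp <- factor(dat$grp)
    by_group <- split(dat$rel_expr, dat$grp)
    if (length(by_group) < 2 || any(lengths(by_group) < 2)) {
      warning(sprintf("family %s lacks groups/replicates; comparisons left NA", fam),
              call. = FALSE)
      next
    }

    small_n <- any(lengths(by_group) < 3)
    if (small_n) {
      warning(sprintf("family %s has a group with n < 3; forcing non-parametric branch",
                      fam), call. = FALSE)
      parametric <- FALSE
    } else {
      parametric <- shapiro_gate(by_group, gate_alpha) &&
        levene_gate(dat$rel_expr, dat$grp, gate_alpha)
    }

    if (parametric) {
      fit <- stats::aov(rel_expr ~ grp, data = dat)
      stat <- summary(fit)[[1]][["F value"]][1]
      tk <- stats::TukeyHSD(fit)$grp
      pair_p <- function(a, b) {
        rn <- rownames(tk)
        hit <- match(paste(a, b, sep = "-"), rn)
        if (is.na(hit)) hit <- match(paste(b, a, sep = "-"), rn)
        tk[hit, "p adj"]
      }
      branch <- "anova_tukey"
    } else {
      kw <- stats::kruskal.test(dat$rel_expr, dat$grp)
      stat <- unname(kw$statistic)
      dn <- dunn_test(dat$rel_expr, dat$grp)
      pair_p <- function(a, b) {
        hit <- which((dn$group_a == a & dn$group_b == b) |
                       (dn$group_a == b & dn$group_b == a))
        dn$p_adj[hit]
      }
      branch <- "kruskal_dunn_bonferroni"
    }

    for (i in idx) {
      a <- grp_key(comparisons$a_treatment[i], comparisons$a_time[i])
      b <- grp_key(comparisons$b_treatment[i], comparisons$b_time[i])
      out$branch[i] <- branch
      out$statistic[i] <- stat
      out$p[i] <- pair_p(a, b)
    }
  }
  ok <- !is.na(out$p)
  out$stars <- NA_character_
  out$stars[ok] <- significance_stars(out$p[ok])
  out$family <- NULL
  out
}
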