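# Independent oracles used across the suite. Deliberately naive: counting
# ranks, explicit sums and full enumeration, sharing no code with the package.

# fractional (average) ranks by counting comparisons
counting_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    smaller <- sum(x < x[i])
    equal <- sum(x == x[i])
    smaller + (equal + 1) / 2
  }, numeric(1))
}

# Spearman rho as Pearson on counting ranks, written out as explicit sums
spearman_oracle <- function(x, y) {
  rx <- counting_ranks(x)
  ry <- counting_ranks(y)
  n <- length(x)
  sxy <- sum((rx - sum(rx) / n) * (ry - sum(ry) / n))
  sxx <- sum((rx - sum(rx) / n)^2)
  syy <- sum((ry - sum(ry) / n)^2)
  sxy / sqrt(sxx * syy)
}

# exact two-sided two-sample permutation test on the difference of means
permutation_test_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  obs <- abs(mean(a) - mean(b))
  stats <- apply(idx, 2, function(ii) {
    abs(mean(pooled[ii]) - mean(pooled[-ii]))
  })
  mean(stats >= obs - 1e-12)
}

# convenience: a tiny noise-free expression table built by hand (not via the
# package's Ct simulator) with one control arm fixed at 1
manual_expression <- function(values_by_group, gene = "g", time_h = 3) {
  rows <- lapply(names(values_by_group), function(tr) {
    v <- values_by_group[[tr]]
    tibble::tibble(gene = gene, treatment = tr, time_h = time_h,
                   bio_rep = seq_along(v), rel_expr = v)
  })
  dplyr::bind_rows(rows)
}
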