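#' Simulate a gapped pairwise protein alignment with known column structure
#'
#' Draws each alignment column from one of four categories at the stated
#' rates: identical residue, conservative substitution (two distinct
#' residues from the same physicochemical class), single gap (one sequence
#' gapped, the other carrying a residue), and non-conservative substitution
#' (residues from two different classes; the remaining probability mass).
#' Columns gapped in both sequences are only produced when `p_double_gap`
#' is set above zero.
#'
#' @param length Number of alignment columns (>= 1).
#' @param p_identity,p_conservative,p_gap Column-category probabilities;
#'   their sum (plus `p_double_gap`) must be <= 1, the remainder going to
#'   non-conservative columns.
#' @param seed Integer seed (reproducible).
#' @param p_double_gap Probability of a column gapped in both sequences
#'   (default 0).
#' @param classes Residue class map (see [default_residue_classes()]).
#'
#' @return An `aligned_pair` object (see [aligned_pair()]) with an extra
#'   `truth` element: the generated per-column category labels.
#' @export
generate_alignment_pair <- function(length, p_identity = 0.6,
                                    p_conservative = 0.2, p_gap = 0.1,
                                    seed = 1L, p_double_gap = 0,
                                    classes = default_residue_classes()) {
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  p <- c(identical = p_identity, conservative = p_conservative,
         single_gap = p_gap, double_gap = p_double_gap)
  if (any(p < 0) || sum(p) > 1 + 1e-12) {
    stop("column probabilities must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  p <- c(p, nonconservative = max(0, 1 - sum(p)))
  set.seed(as.integer(seed))

  by_class <- split(names(classes), classes)
  multi <- by_class[vapply(by_class, length, 1L) >= 2]
  residues <- names(classes)

  cats <- sample(names(p), length, replace = TRUE, prob = p)
  q <- s <- character(length)
  for (i in seq_len(length)) {
    switch(cats[i],
      identical = {
        q[i] <- s[i] <- sample(residues, 1)
      },
      conservative = {
        cls <- multi[[sample(length(multi), 1)]]
        pick <- sample(cls, 2)
        q[i] <- pick[1]; s[i] <- pick[2]
      },
      single_gap = {
        r <- sample(residues, 1)
        if (stats::runif(1) < 0.5) { q[i] <- "-"; s[i] <- r } else { q[i] <- r; s[i] <- "-" }
      },
      double_gap = {
        q[i] <- "-"; s[i] <- "-"
      },
      nonconservative = {
        c1 <- sample(unique(classes), 1)
        c2 <- sample(setdiff(unique(classes), c1), 1)
        q[i] <- sample(by_class[[c1]], 1)
        s[i] <- sample(by_class[[c2]], 1)
      })
  }
  pair <- aligned_pair(paste(q, collapse = ""), paste(s, collapse = ""),
                       query_id = "synthetic_query", subject_id = "synthetic_subject")
  pair$truth <- cats
  pair
}
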