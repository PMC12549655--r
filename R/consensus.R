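#' Physicochemical residue classes
#'
#' The default grouping of the 20 standard amino acids into five
#' physicochemical classes used to decide whether a substitution is
#' conservative: hydrophobic (A, V, L, I, M, F, W), positively charged
#' (K, R, H), negatively charged (D, E), polar uncharged (S, T, N, Q, Y)
#' and special (C, G, P). The map is data, not code: pass a modified copy
#' (or load one from YAML with [read_residue_classes()]) to move residues
#' between classes, e.g. to treat histidine as polar.
#'
#' @return Named character vector: residue -> class label.
#' @export
default_residue_classes <- function() {
  c(A = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
    M = "hydrophobic", F = "hydrophobic", W = "hydrophobic",
    K = "positive", R = "positive", H = "positive",
    D = "negative", E = "negative",
    S = "polar_uncharged", T = "polar_uncharged", N = "polar_uncharged",
    Q = "polar_uncharged", Y = "polar_uncharged",
    C = "special", G = "special", P = "special")
}

#' @rdname default_residue_classes
#' @param path YAML file mapping class label -> vector of residues.
#' @export
read_residue_classes <- function(path) {
  y <- yaml::read_yaml(path)
  out <- unlist(lapply(names(y), function(cl) {
    stats::setNames(rep(cl, length(y[[cl]])), toupper(unlist(y[[cl]])))
  }))
  validate_residue_classes(out)
}

validate_residue_classes <- function(classes) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!setequal(names(classes), std) || anyDuplicated(names(classes))) {
    stop("residue class map must cover each of the 20 standard residues exactly once",
         call. = FALSE)
  }
  classes
}

# residues accepted in alignments beyond the 20 standard ones; treated as a
# non-conservative partner unless identical to the other symbol
AMBIGUOUS_RESIDUES <- c("B", "Z", "X", "U")

#' Construct / read a pairwise protein alignment
#'
#' `aligned_pair()` builds the container from two equal-length gapped
#' sequences; `read_aligned_pair()` parses an aligned FASTA file holding
#' exactly two records (query first, subject second). Sequences are
#' upper-cased; allowed symbols are the 20 standard residues, the
#' ambiguity codes B/Z/X/U and the gap character `-`.
#'
#' @param query_seq,subject_seq Gapped amino-acid strings of equal length.
#' @param query_id,subject_id Record identifiers.
#' @return An object of class `aligned_pair`.
#' @export
aligned_pair <- function(query_seq, subject_seq,
                         query_id = "query", subject_id = "subject") {
  query_seq <- toupper(query_seq)
  subject_seq <- toupper(subject_seq)
  if (nchar(query_seq) != nchar(subject_seq)) {
    stop(sprintf("aligned sequences differ in length (%d vs %d)",
                 nchar(query_seq), nchar(subject_seq)), call. = FALSE)
  }
  if (nchar(query_seq) < 1) stop("empty alignment", call. = FALSE)
  allowed <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], AMBIGUOUS_RESIDUES, "-")
  chars <- unique(c(strsplit(query_seq, "")[[1]], strsplit(subject_seq, "")[[1]]))
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0) {
    stop("illegal alignment character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(query_id = query_id, subject_id = subject_id,
                 query_seq = query_seq, subject_seq = subject_seq),
            class = "aligned_pair")
}

#' @rdname aligned_pair
#' @param path Aligned FASTA file with exactly 2 records.
#' @export
read_aligned_pair <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2) {
    stop(sprintf("aligned FASTA must contain exactly 2 records, found %d",
                 length(recs)), call. = FALSE)
  }
  aligned_pair(as.character(recs[[1]]), as.character(recs[[2]]),
               query_id = names(recs)[1], subject_id = names(recs)[2])
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %s / %s, %d columns\n",
              x$query_id, x$subject_id, nchar(x$query_seq)))
  invisible(x)
}

#' Classify one alignment column
#'
#' Column outcomes, evaluated in order: both symbols equal and not a gap ->
#' `identical`; both gaps -> `double_gap`; exactly one gap -> `single_gap`;
#' both residues in the same physicochemical class -> `conservative`;
#' otherwise `nonconservative`. Ambiguity codes (B, Z, X, U) are never
#' class members, so they yield `nonconservative` unless identical.
#'
#' @param q,s Single characters: residue or `-` (vectors are processed
#'   elementwise).
#' @param classes Residue class map (default [default_residue_classes()]).
#' @return Character vector of outcome labels.
#' @export
classify_column <- function(q, s, classes = default_residue_classes()) {
  classes <- validate_residue_classes(classes)
  allowed <- c(names(classes), AMBIGUOUS_RESIDUES, "-")
  bad <- setdiff(unique(c(q, s)), allowed)
  if (length(bad) > 0) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cq <- unname(classes[q])
  cs <- unname(classes[s])
  dplyr::case_when(
    q == "-" & s == "-" ~ "double_gap",
    q == s ~ "identical",
    q == "-" | s == "-" ~ "single_gap",
    !is.na(cq) & !is.na(cs) & cq == cs ~ "conservative",
    TRUE ~ "nonconservative"
  )
}

#' Derive the conservative consensus of a pairwise alignment
#'
#' Parses the alignment column by column and emits, per column: the shared
#' residue when identical; the query residue at conservative substitutions
#' (query-biased by design -- the query is the organism under study); `X`
#' at non-conservative substitutions (ambiguity marker); the present
#' residue at single-gap columns; `-` at double-gap columns. The consensus
#' always has the alignment's length.
#'
#' @param pair An [aligned_pair()].
#' @param classes Residue class map.
#' @param id Identifier for the consensus record (default
#'   `"consensus_<query_id>"`).
#' @return An object of class `consensus_sequence`: list with `id`,
#'   `sequence`, and `columns`, a tibble (`position`, `query`, `subject`,
#'   `outcome`, `consensus`).
#' @export
derive_consensus <- function(pair, classes = default_residue_classes(),
                             id = NULL) {
  stopifnot(inherits(pair, "aligned_pair"))
  q <- strsplit(pair$query_seq, "")[[1]]
  s <- strsplit(pair$subject_seq, "")[[1]]
  outcome <- classify_column(q, s, classes)
  cons <- dplyr::case_when(
    outcome == "identical" ~ q,
    outcome == "conservative" ~ q,
    outcome == "nonconservative" ~ "X",
    outcome == "single_gap" ~ ifelse(q == "-", s, q),
    outcome == "double_gap" ~ "-"
  )
  structure(
    list(id = id %||% paste0("consensus_", pair$query_id),
         sequence = paste(cons, collapse = ""),
         columns = tibble::tibble(position = seq_along(q), query = q,
                                  subject = s, outcome = outcome,
                                  consensus = cons)),
    class = "consensus_sequence"
  )
}

#' @export
print.consensus_sequence <- function(x, ...) {
  tab <- table(x$columns$outcome)
  cat(sprintf("<consensus_sequence> %s, %d columns (%s)\n", x$id,
              nchar(x$sequence),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Identity and coverage metrics of a pairwise alignment
#'
#' Identity is the fraction of identical columns among columns where both
#' sequences carry a residue, in percent; coverage is the fraction of the
#' query's full-length residues represented (ungapped) in the alignment, in
#' percent. With no both-residue columns, identity is undefined (`NA`).
#'
#' @param pair An [aligned_pair()].
#' @param query_full_length Full length of the (unaligned) query protein;
#'   defaults to the ungapped query length in the alignment (coverage 100).
#' @return A tibble row: `aligned_columns` (both-residue columns),
#'   `identity_pct`, `query_coverage_pct`.
#' @export
alignment_metrics <- function(pair, query_full_length = NULL) {
  stopifnot(inherits(pair, "aligned_pair"))
  q <- strsplit(pair$query_seq, "")[[1]]
  s <- strsplit(pair$subject_seq, "")[[1]]
  both <- q != "-" & s != "-"
  q_res <- sum(q != "-")
  if (is.null(query_full_length)) query_full_length <- q_res
  if (query_full_length < q_res) {
    stop("query_full_length smaller than the ungapped query in the alignment",
         call. = FALSE)
  }
  tibble::tibble(
    aligned_columns = sum(both),
    identity_pct = if (sum(both) == 0) NA_real_
                   else 100 * sum(q == s & both) / sum(both),
    query_coverage_pct = 100 * q_res / query_full_length
  )
}

#' Write a consensus to FASTA and its per-column table to TSV
#'
#' @param consensus A `consensus_sequence`.
#' @param fasta_path Output FASTA path.
#' @param tsv_path Optional per-column TSV path.
#' @return `fasta_path`, invisibly.
#' @export
write_consensus <- function(consensus, fasta_path, tsv_path = NULL) {
  stopifnot(inherits(consensus, "consensus_sequence"))
  seqs <- Biostrings::BStringSet(stats::setNames(consensus$sequence, consensus$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(tsv_path)) {
    readr::write_tsv(consensus$columns, tsv_path)
  }
  invisible(fasta_path)
}

#' @rdname aligned_pair
#' @param pair An `aligned_pair` to write.
#' @param path Output FASTA path.
#' @export
write_aligned_pair <- function(pair, path) {
  stopifnot(inherits(pair, "aligned_pair"))
  seqs <- Biostrings::BStringSet(stats::setNames(
    c(pair$query_seq, pair$subject_seq), c(pair$query_id, pair$subject_id)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
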