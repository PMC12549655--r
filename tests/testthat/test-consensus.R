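test_that("aligned FASTA I/O validates record count, length and alphabet", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q", "KA-DG", ">s", "RACDG"), path)
  pair <- read_aligned_pair(path)
  expect_s3_class(pair, "aligned_pair")
  expect_equal(pair$query_id, "q")
  expect_equal(pair$query_seq, "KA-DG")

  three <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "KK", ">b", "KK", ">c", "KK"), three)
  expect_error(read_aligned_pair(three), "exactly 2")

  lower <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q", "ka-dg", ">s", "racdg"), lower)
  expect_identical(derive_consensus(read_aligned_pair(lower))$sequence,
                   derive_consensus(pair)$sequence)

  expect_error(aligned_pair("KAD", "KA"), "length")
  expect_error(aligned_pair("K1D", "KAD"), "illegal")

  # round trip through write_aligned_pair
  out <- withr::local_tempfile(fileext = ".fasta")
  write_aligned_pair(pair, out)
  expect_equal(read_aligned_pair(out)$subject_seq, pair$subject_seq)
})

test_that("column classification follows the five outcome rules", {
  expect_equal(classify_column("K", "K"), "identical")
  expect_equal(classify_column("K", "R"), "conservative")   # both positive
  expect_equal(classify_column("K", "D"), "nonconservative") # positive vs negative
  expect_equal(classify_column("-", "C"), "single_gap")
  expect_equal(classify_column("A", "-"), "single_gap")
  expect_equal(classify_column("-", "-"), "double_gap")
  expect_error(classify_column("K", "1"), "unknown")
  # ambiguity codes: nonconservative partner unless identical
  expect_equal(classify_column("X", "X"), "identical")
  expect_equal(classify_column("B", "N"), "nonconservative")
  # class-map override: histidine moved to polar makes K/H nonconservative
  classes <- default_residue_classes()
  expect_equal(classify_column("K", "H", classes), "conservative")
  classes["H"] <- "polar_uncharged"
  expect_equal(classify_column("K", "H", classes), "nonconservative")
})

test_that("consensus derivation matches hand-computed fixtures for all outcomes", {
  # K/R conservative -> query K; A/A identical; gap/C -> C; D/D; G/G
  expect_equal(derive_consensus(aligned_pair("KA-DG", "RACDG"))$sequence, "KACDG")
  # both columns cross charge classes
  expect_equal(derive_consensus(aligned_pair("KD", "DK"))$sequence, "XX")
  # all five outcomes in one alignment:
  # K/K identical, L/V conservative (hydrophobic), D/K nonconservative,
  # S/- single gap (query side kept), -/T single gap (subject side kept),
  # -/- double gap
  pair <- aligned_pair("KLDS--", "KVK-T-")
  cons <- derive_consensus(pair)
  expect_equal(cons$sequence, "KLXST-")
  expect_equal(cons$columns$outcome,
               c("identical", "conservative", "nonconservative",
                 "single_gap", "single_gap", "double_gap"))
  # length preserved; X iff nonconservative; '-' iff double gap
  expect_equal(nchar(cons$sequence), nchar(pair$query_seq))
  ch <- strsplit(cons$sequence, "")[[1]]
  expect_identical(ch == "X", cons$columns$outcome == "nonconservative")
  expect_identical(ch == "-", cons$columns$outcome == "double_gap")
})

test_that("query/subject swap only changes conservative columns", {
  set.seed(10)
  for (i in 1:20) {
    pair <- generate_alignment_pair(60, 0.4, 0.25, 0.15, seed = 100 + i)
    fwd <- derive_consensus(pair)
    swapped <- aligned_pair(pair$subject_seq, pair$query_seq)
    rev <- derive_consensus(swapped)
    expect_identical(rev$columns$outcome, fwd$columns$outcome)
    differ <- strsplit(fwd$sequence, "")[[1]] != strsplit(rev$sequence, "")[[1]]
    expect_true(all(fwd$columns$outcome[differ] == "conservative"))
  }
})

test_that("consensus of an X-free consensus with itself is a fixed point", {
  pair <- generate_alignment_pair(120, 0.7, 0.3, 0, seed = 77)
  cons <- derive_consensus(pair)
  expect_false(grepl("X", cons$sequence))
  self <- aligned_pair(cons$sequence, cons$sequence)
  expect_identical(derive_consensus(self)$sequence, cons$sequence)
})

test_that("identity and coverage metrics follow the counting definitions", {
  ident <- aligned_pair(strrep("K", 100), strrep("K", 100))
  m <- alignment_metrics(ident)
  expect_equal(m$identity_pct, 100)
  expect_equal(m$query_coverage_pct, 100)

  # 10 columns: 6 identical, 4 conservative, no gaps
  pair <- aligned_pair("AAAAAAKLDE", "AAAAAARVED")
  m2 <- alignment_metrics(pair)
  expect_equal(m2$identity_pct, 60)
  expect_equal(m2$aligned_columns, 10)

  # alignment covering 50 of 200 query residues
  half <- aligned_pair(strrep("A", 50), strrep("G", 50))
  expect_equal(alignment_metrics(half, query_full_length = 200)$query_coverage_pct, 25)
  expect_error(alignment_metrics(half, query_full_length = 10), "smaller")

  gaps <- aligned_pair("--", "KK")
  expect_true(is.na(alignment_metrics(gaps)$identity_pct))
})

test_that("consensus export writes FASTA and the per-column table", {
  cons <- derive_consensus(aligned_pair("KA-DG", "RACDG"), id = "demo")
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_consensus(cons, fa, tsv)
  back <- Biostrings::readBStringSet(fa)
  expect_equal(names(back), "demo")
  expect_equal(as.character(back[[1]]), "KACDG")
  cols <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(cols), 5)
  expect_equal(cols$outcome[1], "conservative")
})

test_that("residue class maps load from YAML and are validated", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  classes <- default_residue_classes()
  yaml::write_yaml(lapply(split(names(classes), classes), as.list), yml)
  loaded <- read_residue_classes(yml)
  expect_identical(loaded[sort(names(loaded))],
                   classes[sort(names(classes))])
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(hydrophobic = list("A")), bad)
  expect_error(read_residue_classes(bad), "20 standard")
})
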