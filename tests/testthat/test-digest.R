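test_that("trypsin cleaves after K/R but not before proline", {
  expect_identical(tryptic_digest("AKRPGK", 0L)$peptide, c("AK", "RPGK"))
  expect_identical(tryptic_digest("AKRPGK", 1L)$peptide,
                   c("AK", "AKRPGK", "RPGK"))
  expect_identical(nrow(tryptic_digest("", 0L)), 0L)
  # flanking residues and intervals
  dg <- tryptic_digest("AKRPGK", 0L)
  expect_identical(dg$prev_aa, c("-", "K"))
  expect_identical(dg$next_aa, c("R", "-"))
  expect_identical(dg$start, c(0L, 2L))
  expect_identical(dg$end, c(2L, 6L))
})

test_that("zero-missed-cleavage peptides partition arbitrary sequences", {
  set.seed(7)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    s <- paste(sample(alphabet, sample(5:80, 1), replace = TRUE),
               collapse = "")
    dg <- tryptic_digest(s, 0L)
    expect_identical(paste(dg$peptide, collapse = ""), s)
    expect_true(all(dg$missed_cleavages == 0L))
    # substring consistency
    for (j in seq_len(nrow(dg)))
      expect_identical(substr(s, dg$start[j] + 1L, dg$end[j]),
                       dg$peptide[j])
  }
})

test_that("missed-cleavage peptides are concatenations of adjacent bases", {
  set.seed(8)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    s <- paste(sample(alphabet, sample(20:60, 1), replace = TRUE),
               collapse = "")
    base <- tryptic_digest(s, 0L)$peptide
    dg <- tryptic_digest(s, 2L)
    for (j in seq_len(nrow(dg))) {
      m <- dg$missed_cleavages[j]
      runs <- vapply(seq_len(max(length(base) - m, 0L)), function(k)
        paste(base[k:(k + m)], collapse = ""), character(1))
      expect_true(dg$peptide[j] %in% runs)
    }
    # every concatenation of <= m+1 adjacent bases is present
    for (m in 0:2) {
      if (length(base) <= m) next
      runs <- vapply(seq_len(length(base) - m), function(k)
        paste(base[k:(k + m)], collapse = ""), character(1))
      expect_true(all(runs %in% dg$peptide[dg$missed_cleavages == m]))
    }
  }
})

test_that("signal peptides are stripped when digesting mature chains", {
  rec <- blg_record("Bos taurus")
  full <- tryptic_digest(rec, 0L, use_mature = FALSE)
  mat <- tryptic_digest(rec, 0L, use_mature = TRUE)
  expect_identical(paste(mat$peptide, collapse = ""), mature_sequence(rec))
  expect_gt(nchar(paste(full$peptide, collapse = "")),
            nchar(paste(mat$peptide, collapse = "")))
  expect_identical(mat$prev_aa[1], "-")
})

test_that("hamming distance counts differing positions", {
  expect_identical(hamming("AAA", "AAA"), 0L)
  expect_identical(hamming("AAA", "ABC"), 2L)
  expect_error(hamming("AA", "AAA"), "equal lengths")
})

test_that("global identity behaves like an alignment identity", {
  expect_equal(global_identity("PEPTIDE", "PEPTIDE"), 100)
  expect_equal(global_identity("AC", "AG"), 50)
  a <- blg_record("Bos taurus")$sequence
  b <- blg_record("Bos grunniens/mutus")$sequence
  expect_equal(global_identity(a, b), global_identity(b, a))
})
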