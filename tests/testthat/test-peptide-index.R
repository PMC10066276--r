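cow_yak <- blg[blg$taxon %in% c("Bos taurus", "Bos grunniens/mutus"), ]

test_that("shared peptides map to every taxon containing them", {
  idx <- build_peptide_index(cow_yak, tax)
  # the species-differentiating BLG peptide upstream of the terminus is
  # identical in cattle and yak
  expect_setequal(idx$taxa[["TPEVDDEALEK"]],
                  c("Bos taurus", "Bos grunniens/mutus"))
  # the yak terminal peptide is private to yak
  yak_term <- collapse_il(terminal_peptide("Bos grunniens/mutus"))
  expect_identical(idx$taxa[[yak_term]], "Bos grunniens/mutus")
})

test_that("single-record panel maps every peptide to that taxon", {
  one <- blg_record("Ovis aries")
  idx <- build_peptide_index(one, tax)
  expect_true(all(vapply(idx$taxa, identical, logical(1), "Ovis aries")))
  expect_setequal(diagnostic_peptides(idx, "Ovis aries"), names(idx$taxa))
})

test_that("index keys are I/L-collapsed and length-bounded", {
  idx <- build_peptide_index(cow_yak, tax, min_length = 6L,
                             max_length = 30L)
  expect_false(any(grepl("I", names(idx$taxa), fixed = TRUE)))
  expect_true(all(nchar(names(idx$taxa)) >= 6L &
                    nchar(names(idx$taxa)) <= 30L))
  expect_error(build_peptide_index(
    data.frame(accession = "X", taxon = "Martian", protein_class = "whey",
               sequence = "PEPTIDEK", signal_peptide_end = NA_integer_),
    tax), "Martian")
})

test_that("diagnostic peptides agree with a brute-force digest scan", {
  for (taxon in c("Bos grunniens/mutus", "Bos taurus", "Ovis aries",
                  "Cervus elaphus")) {
    idx <- build_peptide_index(blg, tax)
    expect_setequal(diagnostic_peptides(idx, taxon),
                    brute_force_diagnostic(blg, taxon))
  }
  idx2 <- build_peptide_index(cow_yak, tax)
  expect_setequal(diagnostic_peptides(idx2, "Bos grunniens/mutus"),
                  brute_force_diagnostic(cow_yak, "Bos grunniens/mutus"))
  expect_error(diagnostic_peptides(idx2, "Klingon"), "unknown taxon")
})

test_that("yak diagnosticity hinges on the terminal BLG-E peptide", {
  idx <- build_peptide_index(cow_yak, tax)
  yak_term <- collapse_il(terminal_peptide("Bos grunniens/mutus"))
  expect_true(yak_term %in% diagnostic_peptides(idx, "Bos grunniens/mutus"))
  # nothing diagnostic of cattle is shared with yak
  cow_diag <- diagnostic_peptides(idx, "Bos taurus")
  for (p in cow_diag)
    expect_false("Bos grunniens/mutus" %in% idx$taxa[[p]])
})

test_that("adding a record never shrinks an entry's taxon set", {
  small <- blg[blg$taxon %in% c("Bos taurus", "Ovis aries"), ]
  idx_small <- build_peptide_index(small, tax)
  idx_big <- build_peptide_index(blg, tax)
  for (k in names(idx_small$taxa))
    expect_true(all(idx_small$taxa[[k]] %in% idx_big$taxa[[k]]),
                info = k)
  # demotion: peptides diagnostic in the small panel may be shared in the
  # big one, but never the other way round
  expect_true(all(diagnostic_peptides(idx_big, "Bos taurus") %in%
                    diagnostic_peptides(idx_small, "Bos taurus")))
})

test_that("terminal-peptide divergence increases with phylogenetic distance", {
  cow <- terminal_peptide("Bos taurus")
  yak <- terminal_peptide("Bos grunniens/mutus")
  sheep <- terminal_peptide("Ovis aries")
  expect_gt(hamming(sheep, cow), hamming(yak, cow))
})
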