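test_that("PSM tables round-trip through the TSV dialect", {
  psms <- psm_df(c("PEPTIDEK", "ELVISLIVESK"), accession = c("A1", "A2"),
                 mods = c("3:deamidated;5:oxidation", ""))
  f <- tempfile(fileext = ".tsv")
  write_psm_table(psms, f)
  back <- read_psm_table(f)
  expect_identical(back$peptide, psms$peptide)
  expect_identical(back$mods, psms$mods)
  expect_equal(back$e_value, psms$e_value)
})

test_that("reader reports missing columns and bad numbers by position", {
  f <- tempfile(fileext = ".tsv")
  writeLines("sample_id\tpeptide", f)
  expect_error(read_psm_table(f), "spectrum_id")
  writeLines(c(paste(c("sample_id", "spectrum_id", "protein_accession",
                       "peptide", "prev_aa", "next_aa", "e_value",
                       "ion_score", "mods"), collapse = "\t"),
               "S1\tsp1\tA1\tPEPK\tK\tG\tabc\t50\t"), f)
  expect_error(read_psm_table(f), "line 2")
  writeLines(paste(c("sample_id", "spectrum_id", "protein_accession",
                     "peptide", "prev_aa", "next_aa", "e_value",
                     "ion_score", "mods"), collapse = "\t"), f)
  expect_identical(nrow(read_psm_table(f)), 0L)
})

test_that("e-value filter is strict above the threshold", {
  psms <- psm_df(c("AAAAAAK", "CCCCCCK", "DDDDDDK"),
                 accession = "A1", e_value = c(0.02, 0.01, 1e-4))
  out <- filter_psms(psms, filter_params())
  expect_setequal(out$peptide, c("CCCCCCK", "DDDDDDK"))  # 0.01 retained
})

test_that("proteins need two distinct collapsed peptides to survive", {
  psms <- rbind(
    psm_df(c("AAAAAAK", "AAAAAAK"), accession = "ONEPEP"),
    psm_df(c("PEPTIDEK", "PEPTLDEK"), accession = "ILPAIR"),
    psm_df(c("CCCCCCK", "DDDDDDK"), accession = "TWOPEP"))
  counts <- unique_peptides_per_protein(psms)
  expect_identical(counts[["ONEPEP"]], 1L)
  expect_identical(counts[["ILPAIR"]], 1L)  # I/L collapse merges the pair
  expect_identical(counts[["TWOPEP"]], 2L)
  out <- filter_psms(psms, filter_params())
  expect_setequal(unique(out$protein_accession), "TWOPEP")
  # spectrum-based uniqueness keeps the I/L pair
  out2 <- filter_psms(psms, filter_params(uniqueness = "spectrum"))
  expect_true("ILPAIR" %in% out2$protein_accession)
})

test_that("support is counted over e-value survivors only", {
  psms <- psm_df(c("AAAAAAK", "CCCCCCK"), accession = "A1",
                 e_value = c(1e-4, 0.5))
  # the second peptide fails the e-value step, leaving single support
  expect_identical(nrow(filter_psms(psms, filter_params())), 0L)
})

test_that("filtration is idempotent, order-independent, and monotone", {
  set.seed(11)
  peps <- paste0(replicate(40, paste(sample(LETTERS[c(1, 3:8)],
                                            7, replace = TRUE),
                                     collapse = "")), "K")
  psms <- psm_df(peps, accession = sample(paste0("P", 1:8), 40,
                                          replace = TRUE),
                 e_value = 10^runif(40, -6, 0))
  p <- filter_params()
  once <- filter_psms(psms, p)
  expect_identical(filter_psms(once, p), once)
  # permutation equivariance: retained set independent of row order
  perm <- psms[sample(nrow(psms)), ]
  expect_setequal(filter_psms(perm, p)$spectrum_id, once$spectrum_id)
  # relaxing either parameter never drops a previously retained PSM
  relaxed_e <- filter_psms(psms, filter_params(max_e_value = 0.1))
  relaxed_u <- filter_psms(psms, filter_params(
    min_unique_psms_per_protein = 1L))
  expect_true(all(once$spectrum_id %in% relaxed_e$spectrum_id))
  expect_true(all(once$spectrum_id %in% relaxed_u$spectrum_id))
})
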