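test_that("peptide LCAs resolve to the expected taxonomic levels", {
  idx <- build_peptide_index(blg, tax)
  yak_term <- terminal_peptide("Bos grunniens/mutus")
  a <- assign_lca(yak_term, idx, tax)
  expect_identical(a$lca, "Bos grunniens/mutus")
  expect_true(a$informative)
  expect_identical(a$food_class, "milk_whey")
  # shared across the three Bos species only -> genus Bos
  b <- assign_lca("VLVLDTDYK", idx, tax)
  expect_identical(b$lca, "Bos")
  expect_setequal(b$matched_taxa, c("Bos taurus", "Bos indicus",
                                    "Bos grunniens/mutus"))
  # shared by all bovids (cattle and sheep among them) -> Bovidae
  d <- assign_lca("GLDIQK", idx, tax)
  expect_identical(d$lca, "Bovidae")
  expect_true(d$informative)
  # absent from the reference space
  u <- assign_lca("WWWWWWWWK", idx, tax)
  expect_identical(u$lca, "unassigned")
  expect_false(u$informative)
})

test_that("a peptide shared by ruminants and equids is uninformative", {
  two <- data.frame(
    accession = c("T1", "T2"),
    taxon = c("Bos taurus", "Equus caballus"),
    protein_class = "whey",
    sequence = c("SHAREDPEPK", "SHAREDPEPK"),
    signal_peptide_end = NA_integer_, stringsAsFactors = FALSE)
  idx <- build_peptide_index(two, tax)
  a <- assign_lca("SHAREDPEPK", idx, tax)
  expect_identical(a$lca, "Mammalia")
  expect_false(a$informative)
})

test_that("Equus-level calls are informative at and below the genus", {
  idx <- build_peptide_index(panel, tax)
  eq <- Filter(function(k) identical(sort(idx$taxa[[k]]),
                                     sort(c("Equus caballus",
                                            "Equus asinus"))),
               names(idx$taxa))
  expect_gt(length(eq), 0)
  a <- assign_lca(eq[[1]], idx, tax)
  expect_identical(a$lca, "Equus")
  expect_true(a$informative)
})

test_that("class conflicts resolve conservatively to 'other'", {
  two <- data.frame(
    accession = c("MILK1", "CONT1"),
    taxon = c("Bos taurus", "Bos taurus"),
    protein_class = c("whey", "env_contaminant"),
    sequence = c("SHAREDPEPK", "SHAREDPEPK"),
    signal_peptide_end = NA_integer_, stringsAsFactors = FALSE)
  idx <- build_peptide_index(two, tax)
  a <- assign_lca("SHAREDPEPK", idx, tax)
  expect_identical(a$food_class, "other")
  # and such peptides never enter dietary summaries
  s <- summarize_dietary(psm_df("SHAREDPEPK", accession = "MILK1"),
                         idx, tax)
  expect_identical(s$totals$n_informative_peptides, 0L)
  expect_match(s$totals$flag, "no dietary evidence")
})

test_that("enlarging the matched set only moves the LCA rootward", {
  set.seed(13)
  mam <- c("Bos taurus", "Bos indicus", "Bos grunniens/mutus",
           "Bison bison", "Ovis aries", "Capra hircus", "Cervus elaphus",
           "Equus caballus", "Equus asinus")
  for (i in 1:30) {
    taxa <- sample(mam, sample(1:5, 1))
    extra <- sample(setdiff(mam, taxa), 1)
    lca1 <- taxon_lca(tax, taxa)
    lca2 <- taxon_lca(tax, c(taxa, extra))
    expect_true(taxon_is_descendant(tax, lca1, lca2),
                info = paste(lca1, "->", lca2))
  }
})

test_that("assignment is independent of taxon iteration order", {
  idx <- build_peptide_index(blg, tax)
  idx_rev <- build_peptide_index(blg[rev(seq_len(nrow(blg))), ], tax)
  for (k in c("GLDLQK", "LLVTQTMK", "VLVLDTDYK"))
    expect_identical(assign_lca(k, idx, tax)$lca,
                     assign_lca(k, idx_rev, tax)$lca, info = k)
})

test_that("dietary proportions sum to one over informative PSMs", {
  idx <- build_peptide_index(panel, tax)
  cfg <- khorig_like_config(seed = 3)
  sim <- simulate_sample(cfg, 6, panel = panel, tree = tax, index = idx)
  flt <- filter_psms(sim$psms, filter_params())
  s <- summarize_dietary(flt, idx, tax)
  b <- s$by_taxon
  expect_equal(sum(b$prop_psms), 1, tolerance = 1e-9)
  expect_equal(sum(b$n_psms), s$totals$n_informative_psms)
})
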