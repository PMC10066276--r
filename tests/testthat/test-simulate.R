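test_that("identical seeds give byte-identical tables", {
  cfg <- khorig_like_config(seed = 5)
  a <- simulate_sample(cfg, 6, panel = panel, tree = tax,
                       index = pep_index)
  b <- simulate_sample(cfg, 6, panel = panel, tree = tax,
                       index = pep_index)
  expect_identical(a$psms, b$psms)
  expect_identical(a$truth, b$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_psm_table(a$psms, f1); write_psm_table(b$psms, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed perturbs the table
  cfg2 <- khorig_like_config(seed = 6)
  c2 <- simulate_sample(cfg2, 6, panel = panel, tree = tax,
                        index = pep_index)
  expect_false(identical(a$psms, c2$psms))
})

test_that("the ledger echoes the requested dietary composition", {
  dietary <- data.frame(
    taxon = c("Bos grunniens/mutus", "Equus", "Pecora"),
    food_class = c("milk_whey", "milk_whey", "milk_whey"),
    n = c(1L, 4L, 3L), stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 7, samples = list(
    list(sample_id = "S1", regime = "well_preserved", dietary = dietary)))
  sim <- simulate_sample(cfg, 1, panel = panel, tree = tax,
                         index = pep_index)
  got <- table(sim$truth$dietary$taxon)
  expect_identical(got[["Bos grunniens/mutus"]], 1L)
  expect_identical(got[["Equus"]], 4L)
  expect_identical(got[["Pecora"]], 3L)
  # planted peptides really have the requested LCA
  for (i in seq_len(nrow(sim$truth$dietary)))
    expect_identical(
      assign_lca(sim$truth$dietary$key[i], pep_index, tax)$lca,
      sim$truth$dietary$taxon[i])
  # flanks come from the true digest context: all dietary PSMs tryptic
  diet_psms <- sim$psms[sim$psms$protein_accession %in%
                          sim$truth$dietary$accession, ]
  expect_true(all(classify_cleavage(diet_psms) == "fully_tryptic"))
})

test_that("requests for peptides the panel cannot provide fail loudly", {
  cfg <- sim_config(seed = 1, samples = list(
    list(sample_id = "S1", regime = "well_preserved",
         dietary = data.frame(taxon = "Homo sapiens",
                              food_class = "milk_whey", n = 1L))))
  expect_error(simulate_sample(cfg, 1, panel = panel, tree = tax,
                               index = pep_index), "Homo sapiens")
})

test_that("degraded samples fail preservation, well-preserved pass", {
  cfg <- sim_config(seed = 19, samples = list(
    list(sample_id = "GOOD", regime = "well_preserved", dietary = NULL),
    list(sample_id = "BAD", regime = "degraded", dietary = NULL)))
  st <- simulate_study(cfg, panel = panel, tree = tax, index = pep_index)
  ossd <- default_ossd_map()
  for (s in st$samples) {
    flt <- filter_psms(s$psms, filter_params())
    r <- assess_preservation(flt$protein_accession, ossd,
                             sample_id = s$truth$sample_id)
    expect_identical(r$passed, s$truth$expected_pass,
                     info = s$truth$sample_id)
  }
})

test_that("noise PSMs are filtered out and never reach dietary summaries", {
  dietary <- data.frame(taxon = "Equus", food_class = "milk_whey", n = 3L)
  cfg <- sim_config(seed = 23, samples = list(
    list(sample_id = "S1", regime = "well_preserved", dietary = dietary)),
    noise_fraction = 0.3)
  sim <- simulate_sample(cfg, 1, panel = panel, tree = tax,
                         index = pep_index)
  expect_gt(sim$truth$n_noise, 0)
  flt <- filter_psms(sim$psms, filter_params())
  expect_true(all(flt$e_value <= 0.01))
  s <- summarize_dietary(flt, pep_index, tax)
  expect_identical(s$totals$n_informative_peptides, 3L)
})

test_that("study writer emits per-sample tables and a manifest", {
  cfg <- sim_config(seed = 31, n_samples = 2, regime = "well_preserved")
  dir <- file.path(tempdir(), "simstudy")
  unlink(dir, recursive = TRUE)
  st <- simulate_study(cfg, dir = dir, panel = panel, tree = tax,
                       index = pep_index)
  expect_setequal(list.files(dir, pattern = "psms.tsv$"),
                  c("SIM-01.psms.tsv", "SIM-02.psms.tsv"))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(length(man), 2L)
  back <- read_psm_table(file.path(dir, "SIM-01.psms.tsv"))
  expect_identical(nrow(back), nrow(st$samples[[1]]$psms))
  # zero samples -> empty manifest
  st0 <- simulate_study(sim_config(seed = 1, n_samples = 0,
                                   samples = list()),
                        panel = panel, tree = tax, index = pep_index)
  expect_identical(length(st0$manifest), 0L)
})

test_that("single-peptide dietary proteins are erased by the filter", {
  dietary <- data.frame(taxon = c("Equus", "Bovidae"),
                        food_class = c("milk_whey", "milk_casein"),
                        n = c(1L, 1L), stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 37, samples = list(
    list(sample_id = "S1", regime = "well_preserved", dietary = dietary)),
    ensure_support = FALSE, psms_per_peptide = c(1L, 1L))
  sim <- simulate_sample(cfg, 1, panel = panel, tree = tax,
                         index = pep_index)
  tab <- table(sim$truth$dietary$accession)
  # a whey and a casein request can never share a protein, so both
  # dietary proteins carry exactly one peptide here
  expect_true(all(tab == 1L))
  flt <- filter_psms(sim$psms, filter_params())
  lone <- names(tab)[tab == 1L]
  expect_false(any(lone %in% flt$protein_accession))
  relaxed <- filter_psms(sim$psms,
                         filter_params(min_unique_psms_per_protein = 1L))
  expect_true(all(lone %in% relaxed$protein_accession))
})
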