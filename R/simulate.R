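# Seeded generator of synthetic calculus PSM tables. A sample is assembled
# from: (i) oral-microbiome / immune / lab- / environmental-contaminant
# proteins at regime-dependent counts, each supported by several distinct
# tryptic peptides; (ii) dietary peptides drawn from the reference panel's
# digest under an LCA constraint (a "Bovidae"-level request draws peptides
# shared across exactly the bovids, a yak request draws yak-diagnostic
# peptides); (iii) log-uniform e-value noise PSMs; (iv) semi-tryptic
# truncations of non-dietary PSMs. A ground-truth ledger accompanies every
# table and is never read by the analysis stages.

FOOD_CLASSES <- c(whey = "milk_whey", casein = "milk_casein",
                  blood_tissue = "blood_tissue")

REGIME_COUNTS <- list(
  well_preserved = list(oral_microbiome = c(25L, 40L), immune = c(6L, 10L),
                        lab_contaminant = c(3L, 5L),
                        env_contaminant = c(3L, 5L)),
  degraded = list(oral_microbiome = c(1L, 3L), immune = c(0L, 2L),
                  lab_contaminant = c(4L, 5L), env_contaminant = c(4L, 5L)))

#' Simulation configuration
#'
#' Defines the study a synthetic PSM dataset emulates. Per-sample specs
#' carry a preservation regime (`"well_preserved"` samples draw many oral
#' and immune proteins and pass the OSSD assessment with high probability;
#' `"degraded"` samples are contaminant-dominated and fail) and an optional
#' dietary composition: a data frame with columns `taxon`, `food_class`
#' (`milk_whey`, `milk_casein`, `blood_tissue`) and `n` (distinct peptides
#' whose least common ancestor must be exactly that taxon).
#'
#' @param seed integer master seed; every sample derives its own stream
#'   from it.
#' @param n_samples number of samples (ignored when `samples` is given).
#' @param samples optional list of per-sample specs, each a list with
#'   `sample_id`, `regime`, and `dietary` (data frame or `NULL`).
#' @param regime default preservation regime.
#' @param dietary default dietary composition data frame (or `NULL`).
#' @param peptides_per_protein range of distinct peptides supporting each
#'   non-dietary protein.
#' @param psms_per_peptide range of PSM multiplicity per peptide.
#' @param signal_log10e,noise_log10e log10 e-value ranges for credible and
#'   noise PSMs (defaults: signal in `[-8, -2.2]`, i.e. e-values well below
#'   the 0.01 cut; noise in `[-2, 0]`).
#' @param noise_fraction fraction of additional junk PSMs (e-value above
#'   the cut) appended to each sample.
#' @param semi_tryptic_fraction probability that a non-dietary PSM is
#'   truncated at one terminus (diagenetic/in-source truncation). Dietary
#'   PSMs are left fully tryptic, mirroring the empirical pattern that
#'   non-tryptic peptides are overwhelmingly contaminant collagen/keratin.
#' @param deamidation_rate per-N/Q-site deamidation probability ("ancient"
#'   damage flavour; no analysis stage consumes it).
#' @param oxidation_rate per-M-site oxidation probability.
#' @param ensure_support keep dietary draws co-located so every dietary
#'   protein carries at least two distinct peptides and survives the
#'   protein-support filter (default `TRUE`).
#' @return A `sim_config` list with a normalized `samples` element.
#' @export
sim_config <- function(seed = 1L, n_samples = 1L, samples = NULL,
                       regime = "well_preserved", dietary = NULL,
                       peptides_per_protein = c(2L, 4L),
                       psms_per_peptide = c(1L, 3L),
                       signal_log10e = c(-8, -2.2),
                       noise_log10e = c(-2, 0),
                       noise_fraction = 0.05,
                       semi_tryptic_fraction = 0.1,
                       deamidation_rate = 0.3,
                       oxidation_rate = 0.2,
                       ensure_support = TRUE) {
  stopifnot(noise_fraction >= 0, noise_fraction <= 1,
            semi_tryptic_fraction >= 0, semi_tryptic_fraction <= 1,
            deamidation_rate >= 0, deamidation_rate <= 1)
  if (is.null(samples)) {
    samples <- lapply(seq_len(n_samples), function(i)
      list(sample_id = sprintf("SIM-%02d", i), regime = regime,
           dietary = dietary))
  }
  for (s in samples) {
    stopifnot(s$regime %in% names(REGIME_COUNTS))
    if (!is.null(s$dietary)) {
      stopifnot(all(c("taxon", "food_class", "n") %in% names(s$dietary)))
      stopifnot(all(s$dietary$food_class %in% FOOD_CLASSES))
      stopifnot(all(s$dietary$n >= 0))
    }
  }
  structure(list(seed = as.integer(seed), samples = samples,
                 peptides_per_protein = peptides_per_protein,
                 psms_per_peptide = psms_per_peptide,
                 signal_log10e = signal_log10e,
                 noise_log10e = noise_log10e,
                 noise_fraction = noise_fraction,
                 semi_tryptic_fraction = semi_tryptic_fraction,
                 deamidation_rate = deamidation_rate,
                 oxidation_rate = oxidation_rate,
                 ensure_support = ensure_support),
            class = "sim_config")
}

# deterministic per-sample stream seed, kept below 2^31
sample_seed <- function(seed, sample_index) {
  (as.numeric(seed) * 48271 + sample_index * 16807) %% 2147483647
}

# digest context of one panel record: raw peptide, collapsed key, flanks
record_digest <- function(record, max_missed = 1L) {
  dg <- tryptic_digest(record, max_missed_cleavages = max_missed)
  dg$key <- collapse_il(dg$peptide)
  dg
}

#' Precomputed simulation context
#'
#' Digest tables for every panel record plus the LCA/food-class annotation
#' of every indexed peptide. Deterministic; compute once per study.
#'
#' @param panel reference `protein_panel`.
#' @param tree a [taxonomy_tree()].
#' @param index a [build_peptide_index()] over `panel`.
#' @return list with `digests` (per accession) and `cand`.
#' @export
sim_context <- function(panel, tree, index) {
  digests <- lapply(seq_len(nrow(panel)), function(i)
    record_digest(panel[i, , drop = FALSE],
                  index$params$max_missed_cleavages))
  names(digests) <- panel$accession
  list(digests = digests, cand = dietary_candidates(index, tree))
}

# candidate dietary peptides: one row per indexed peptide with its exact
# LCA, food class, and containing accessions
dietary_candidates <- function(index, tree) {
  keys <- names(index$taxa)
  lca <- vapply(keys, function(k) taxon_lca(tree, index$taxa[[k]]),
                character(1))
  cls <- vapply(keys, function(k) {
    cc <- index$classes[[k]]
    if (length(cc) == 1L && cc %in% names(FOOD_CLASSES))
      FOOD_CLASSES[[cc]] else "other"
  }, character(1))
  list(key = keys, lca = unname(lca), food_class = unname(cls))
}

mods_for <- function(peptide, deam_rate, ox_rate) {
  aa <- strsplit(peptide, "")[[1L]]
  mods <- character(0)
  nq <- which(aa %in% c("N", "Q"))
  if (length(nq)) {
    hit <- nq[stats::runif(length(nq)) < deam_rate]
    mods <- c(mods, sprintf("%d:deamidated", hit))
  }
  mm <- which(aa == "M")
  if (length(mm)) {
    hit <- mm[stats::runif(length(mm)) < ox_rate]
    mods <- c(mods, sprintf("%d:oxidation", hit))
  }
  cc <- which(aa == "C")
  if (length(cc)) mods <- c(mods, sprintf("%d:carbamidomethyl", cc))
  paste0(mods, collapse = ";")
}

# draw dietary peptides for one sample under the exact-LCA constraint.
# Accessions are planned deterministically before peptides are sampled:
# draws are clustered onto as few proteins as possible (each cluster the
# protein able to host the most outstanding draws), so every dietary
# protein carries several distinct peptides and survives the
# protein-support filter; which pool peptide fills each slot is random.
draw_dietary <- function(dietary, cand, index, tree, ensure_support) {
  empty <- data.frame(key = character(0), accession = character(0),
                      taxon = character(0), food_class = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(dietary) || nrow(dietary) == 0L) return(empty)
  depth <- vapply(dietary$taxon, function(t)
    length(taxon_ancestors(tree, t)), integer(1))
  dietary <- dietary[order(-depth), , drop = FALSE]
  pools <- lapply(seq_len(nrow(dietary)), function(r)
    cand$key[cand$lca == dietary$taxon[r] &
               cand$food_class == dietary$food_class[r]])
  for (r in seq_len(nrow(dietary)))
    if (length(pools[[r]]) < dietary$n[r])
      stop("panel has only ", length(pools[[r]]), " ",
           dietary$food_class[r], " peptides with LCA '",
           dietary$taxon[r], "' (", dietary$n[r], " requested)")
  out <- empty
  out$request <- integer(0)
  remaining <- dietary$n
  acc_count <- integer(0)  # named: current cluster sizes
  while (sum(remaining) > 0L) {
    open_pools <- lapply(seq_along(pools), function(r)
      if (remaining[r] > 0L) setdiff(pools[[r]], out$key) else character(0))
    # score each accession by how many outstanding draws it could host;
    # a take that would leave a single stranded draw of a request is
    # trimmed (the lone survivor would later land on an unused protein
    # and be erased by the support filter); existing clusters only break
    # ties
    hosts <- unique(unlist(index$accessions[unlist(open_pools)],
                           use.names = FALSE))
    takes_for <- function(a, strict) {
      vapply(seq_along(open_pools), function(r) {
        t <- min(remaining[r],
                 sum(vapply(open_pools[[r]], function(k)
                   a %in% index$accessions[[k]], logical(1))))
        if (strict && remaining[r] - t == 1L) t <- t - 1L
        max(t, 0L)
      }, integer(1))
    }
    strict <- TRUE
    gain <- vapply(hosts, function(a) sum(takes_for(a, TRUE)), integer(1))
    if (max(gain) == 0L) {
      strict <- FALSE
      gain <- vapply(hosts, function(a) sum(takes_for(a, FALSE)),
                     integer(1))
    }
    cluster <- ifelse(hosts %in% names(acc_count), acc_count[hosts], 0L)
    best <- hosts[order(-gain, -cluster, hosts)][1L]
    takes <- takes_for(best, strict)
    for (r in seq_along(open_pools)) {
      if (takes[r] == 0L) next
      avail <- open_pools[[r]][vapply(open_pools[[r]], function(k)
        best %in% index$accessions[[k]], logical(1))]
      picks <- avail[sample.int(length(avail), takes[r])]
      out <- rbind(out, data.frame(key = picks, accession = best,
                                   taxon = dietary$taxon[r],
                                   food_class = dietary$food_class[r],
                                   request = r,
                                   stringsAsFactors = FALSE))
      remaining[r] <- remaining[r] - takes[r]
    }
    acc_count[best] <- sum(out$accession == best)
    if (sum(takes) == 0L)
      stop("cannot place dietary peptides for: ",
           paste(unique(dietary$taxon[remaining > 0L]), collapse = ", "))
  }
  if (ensure_support && nrow(out) > 0L) {
    for (iter in seq_len(nrow(out) + 1L)) {
      tab <- table(out$accession)
      singles <- names(tab)[tab == 1L]
      if (!length(singles)) break
      progress <- FALSE
      for (a in singles) {
        i <- which(out$accession == a)
        other <- setdiff(unique(out$accession), a)
        # relocate: the same peptide also occurs in another used protein
        alt <- intersect(index$accessions[[out$key[i]]], other)
        if (length(alt)) {
          out$accession[i] <- alt[1L]
          progress <- TRUE
          break
        }
        # swap: replace with an unchosen pool-mate of the same request
        # that is reachable from another used protein
        for (q in setdiff(pools[[out$request[i]]], out$key)) {
          altq <- intersect(index$accessions[[q]], other)
          if (length(altq)) {
            out$key[i] <- q
            out$accession[i] <- altq[1L]
            progress <- TRUE
            break
          }
        }
        if (progress) break
      }
      if (!progress) break
    }
    tab <- table(out$accession)
    if (any(tab == 1L))
      stop("cannot co-locate dietary peptides for protein support on: ",
           paste(names(tab)[tab == 1L], collapse = ", "),
           "; request at least two peptides reachable from each protein")
  }
  out$request <- NULL
  out
}

#' Simulate one calculus PSM table
#'
#' Deterministic given `(config, sample_index)`: the same pair always
#' yields byte-identical tables. Dietary peptides are drawn from the
#' reference panel digest so that each request's least-common-ancestor
#' label is exactly achievable, with flanking residues taken from the true
#' digest context; the accompanying ground-truth ledger records what was
#' planted.
#'
#' @param config a [sim_config()].
#' @param sample_index 1-based index into `config$samples`.
#' @param panel reference panel (default [synthetic_metaproteome_panel()]).
#' @param tree taxonomy (default [default_taxonomy()]).
#' @param index optional prebuilt [build_peptide_index()] over `panel`.
#' @param context optional precomputed [sim_context()] (digests and
#'   LCA-annotated candidate peptides); built on the fly when absent.
#' @return list with `psms` (PSM data frame) and `truth` (ledger: sample
#'   id, regime, planted protein accessions per OSSD category, dietary
#'   draws with taxon/food-class labels, noise and semi-tryptic counts).
#' @export
simulate_sample <- function(config, sample_index, panel = NULL, tree = NULL,
                            index = NULL, context = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree)) tree <- default_taxonomy()
  if (is.null(panel)) panel <- synthetic_metaproteome_panel(tree)
  if (is.null(index)) index <- build_peptide_index(panel, tree)
  if (is.null(context)) context <- sim_context(panel, tree, index)
  spec <- config$samples[[sample_index]]
  with_seed(sample_seed(config$seed, sample_index), {
    cand <- context$cand
    digests <- context$digests
    rows <- list()
    emit <- function(acc, raw, prev, nxt, e) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = spec$sample_id,
        spectrum_id = sprintf("%s.sp%05d", spec$sample_id,
                              length(rows) + 1L),
        protein_accession = acc, peptide = raw, prev_aa = prev,
        next_aa = nxt, e_value = e,
        ion_score = round(stats::runif(1L, 25, 85), 2),
        mods = mods_for(raw, config$deamidation_rate,
                        config$oxidation_rate),
        stringsAsFactors = FALSE)
    }
    sig_e <- function() 10^stats::runif(1L, config$signal_log10e[1L],
                                        config$signal_log10e[2L])
    rint <- function(rg) if (rg[1L] == rg[2L]) rg[1L] else
      sample(rg[1L]:rg[2L], 1L)
    pick_n <- function(x, n) x[sample.int(length(x), n)]  # safe for len 1
    # --- background (OSSD) proteins -----------------------------------
    counts <- REGIME_COUNTS[[spec$regime]]
    planted <- list()
    for (cat in names(counts)) {
      cat_cls <- switch(cat, oral_microbiome = "microbiome", cat)
      accs <- panel$accession[panel$protein_class == cat_cls]
      n <- rint(counts[[cat]])
      n <- min(n, length(accs))
      take <- if (n > 0L) pick_n(accs, n) else character(0)
      planted[[cat]] <- sort(take)
      for (a in take) {
        dg <- digests[[a]]
        ok <- which(nchar(dg$peptide) >= index$params$min_length &
                      nchar(dg$peptide) <= index$params$max_length &
                      dg$missed_cleavages == 0L)
        npep <- min(rint(config$peptides_per_protein), length(ok))
        for (i in pick_n(ok, npep)) {
          for (m in seq_len(rint(config$psms_per_peptide))) {
            raw <- dg$peptide[i]; prev <- dg$prev_aa[i]; nxt <- dg$next_aa[i]
            if (stats::runif(1L) < config$semi_tryptic_fraction &&
                nchar(raw) >= 8L) {
              cut <- sample(3:(nchar(raw) - 3L), 1L)
              if (stats::runif(1L) < 0.5) {        # N-terminal truncation
                prev <- substr(raw, cut, cut)
                raw <- substr(raw, cut + 1L, nchar(raw))
              } else {                              # C-terminal truncation
                nxt <- substr(raw, cut + 1L, cut + 1L)
                raw <- substr(raw, 1L, cut)
              }
            }
            emit(a, raw, prev, nxt, sig_e())
          }
        }
      }
    }
    # --- dietary peptides ---------------------------------------------
    diet <- draw_dietary(spec$dietary, cand, index, tree,
                         config$ensure_support)
    if (nrow(diet)) {
      for (i in seq_len(nrow(diet))) {
        dg <- digests[[diet$accession[i]]]
        hit <- dg[dg$key == diet$key[i], , drop = FALSE]
        hit <- hit[which.min(hit$missed_cleavages), , drop = FALSE]
        for (m in seq_len(rint(config$psms_per_peptide)))
          emit(diet$accession[i], hit$peptide, hit$prev_aa, hit$next_aa,
               sig_e())
      }
    }
    # --- noise PSMs (e-value above the credibility cut) ---------------
    n_noise <- round(config$noise_fraction * length(rows))
    for (i in seq_len(n_noise)) {
      acc <- sample(panel$accession, 1L)
      raw <- random_block(sample(8:14, 1L))
      emit(acc, raw, sample(c("K", "R"), 1L), sample(SAFE_AA, 1L),
           10^stats::runif(1L, config$noise_log10e[1L],
                           config$noise_log10e[2L]))
    }
    psms <- do.call(rbind, rows)
    rownames(psms) <- NULL
    truth <- list(sample_id = spec$sample_id, regime = spec$regime,
                  expected_pass = spec$regime == "well_preserved",
                  background = planted,
                  dietary = diet,
                  n_noise = n_noise,
                  n_psms = nrow(psms))
    list(psms = psms, truth = truth)
  })
}

#' Simulate a whole study
#'
#' Runs [simulate_sample()] for every sample in the configuration and,
#' optionally, writes per-sample PSM TSVs, a ground-truth manifest (JSON)
#' and the effective configuration (key-value text) to a directory. The
#' manifest is for validation only; no analysis stage reads it.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @param panel,tree,index as in [simulate_sample()].
#' @return list with `samples` (list of `simulate_sample()` results) and
#'   `manifest` (list of truth ledgers).
#' @export
simulate_study <- function(config, dir = NULL, panel = NULL, tree = NULL,
                           index = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree)) tree <- default_taxonomy()
  if (is.null(panel)) panel <- synthetic_metaproteome_panel(tree)
  if (is.null(index)) index <- build_peptide_index(panel, tree)
  context <- sim_context(panel, tree, index)
  res <- lapply(seq_along(config$samples), function(i)
    simulate_sample(config, i, panel = panel, tree = tree, index = index,
                    context = context))
  manifest <- lapply(res, `[[`, "truth")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (r in res)
      write_psm_table(r$psms, file.path(dir, paste0(r$truth$sample_id,
                                                    ".psms.tsv")))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg <- config
    cfg$samples <- NULL
    writeLines(c(sprintf("n_samples = %d", length(config$samples)),
                 vapply(names(cfg), function(k)
                   sprintf("%s = %s", k,
                           paste(format(cfg[[k]]), collapse = ",")),
                   character(1))),
               file.path(dir, "config.txt"))
  }
  list(samples = res, manifest = manifest)
}

#' Study preset mirroring a permafrost calculus cohort
#'
#' Eleven individuals: ten well-preserved samples (one degraded sample that
#' fails the OSSD assessment), eight of the ten passing samples carrying
#' dietary evidence, seven of those eight with horse (Equus) milk, and two
#' with a yak-diagnostic milk peptide. One individual's milk-peptide
#' composition follows the published per-taxon counts for the richest
#' sample of that cohort (1 yak + 12 Equus + 2 Bovinae + 4 Bovidae +
#' 4 Pecora = 23 informative milk peptides).
#'
#' @param seed master seed.
#' @return A [sim_config()].
#' @export
khorig_like_config <- function(seed = 1L) {
  d <- function(...) {
    m <- matrix(c(...), ncol = 3L, byrow = TRUE)
    data.frame(taxon = m[, 1L], food_class = m[, 2L],
               n = as.integer(m[, 3L]), stringsAsFactors = FALSE)
  }
  samples <- list(
    list(sample_id = "HOR-01", regime = "well_preserved",
         dietary = d("Bos grunniens/mutus", "milk_whey", 1,
                     "Bos", "milk_casein", 1,
                     "Bovinae", "milk_casein", 3,
                     "Bovidae", "milk_casein", 2,
                     "Pecora", "milk_whey", 2,
                     "Pecora", "milk_casein", 2,
                     "Pecora", "blood_tissue", 1,
                     "Bovidae", "blood_tissue", 1)),
    list(sample_id = "HOR-08", regime = "well_preserved",
         dietary = d("Ovis aries", "milk_casein", 1,
                     "Caprinae", "milk_casein", 2,
                     "Equus", "milk_casein", 2)),
    list(sample_id = "HOR-13", regime = "well_preserved", dietary = NULL),
    list(sample_id = "HOR-21", regime = "well_preserved", dietary = NULL),
    list(sample_id = "HOR-25", regime = "well_preserved",
         dietary = d("Equus", "milk_whey", 3,
                     "Pecora", "milk_casein", 2)),
    list(sample_id = "HOR-27", regime = "well_preserved",
         dietary = d("Bos grunniens/mutus", "milk_whey", 1,
                     "Equus", "milk_whey", 8,
                     "Equus", "milk_casein", 4,
                     "Bovinae", "milk_casein", 2,
                     "Bovidae", "milk_casein", 4,
                     "Pecora", "milk_whey", 2,
                     "Pecora", "milk_casein", 2,
                     "Pecora", "blood_tissue", 1,
                     "Bovidae", "blood_tissue", 1)),
    list(sample_id = "HOR-30", regime = "well_preserved",
         dietary = d("Equus", "milk_whey", 4,
                     "Bovidae", "milk_casein", 2)),
    list(sample_id = "HOR-40", regime = "well_preserved",
         dietary = d("Equus", "milk_whey", 2,
                     "Caprinae", "milk_casein", 2)),
    list(sample_id = "HOR-48", regime = "well_preserved",
         dietary = d("Equus", "milk_whey", 3,
                     "Pecora", "blood_tissue", 2)),
    list(sample_id = "HOR-58", regime = "degraded", dietary = NULL),
    list(sample_id = "HOR-73", regime = "well_preserved",
         dietary = d("Equus", "milk_casein", 2,
                     "Bovinae", "milk_casein", 2)))
  sim_config(seed = seed, samples = samples)
}
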