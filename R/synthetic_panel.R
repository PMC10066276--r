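# Synthetic reference metaproteome: dietary ortholog families with a
# designed conservation-block structure, plus oral-microbiome, immune and
# contaminant proteins. Everything here is generated deterministically in
# code (fixed internal seed), so the panel is a reproducible fixture rather
# than shipped data.

# letters safe for synthetic blocks: no K/R (cleavage), no P (Keil rule),
# no I (I/L collapse), no C (keeps synthetic peptides modification-simple)
SAFE_AA <- c("A", "D", "E", "F", "G", "H", "L", "M", "N", "Q", "S", "T",
             "V", "W", "Y")

TAXON_CODES <- c("Bos taurus" = "BOSTA", "Bos indicus" = "BOSIN",
                 "Bos grunniens/mutus" = "BOSMU", "Bison bison" = "BISBI",
                 "Ovis aries" = "OVIAR", "Capra hircus" = "CAPHI",
                 "Cervus elaphus" = "CEREL", "Equus caballus" = "EQUCA",
                 "Equus asinus" = "EQUAS")

RUMINANTS <- c("Bos taurus", "Bos indicus", "Bos grunniens/mutus",
               "Bison bison", "Ovis aries", "Capra hircus",
               "Cervus elaphus")
EQUIDS <- c("Equus caballus", "Equus asinus")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

random_block <- function(len = NULL) {
  if (is.null(len)) len <- sample(9:14, 1L)
  paste0(paste0(sample(SAFE_AA, len - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

# deterministic single-substitution variant for the i-th outside member;
# variants are pairwise distinct and distinct from the base
block_variant <- function(base, i) {
  aa <- strsplit(base, "")[[1L]]
  n <- length(aa)
  pos <- ((i - 1L) %% (n - 1L)) + 1L
  shift <- 1L + (i - 1L) %/% (n - 1L)
  cur <- match(aa[pos], SAFE_AA)
  if (is.na(cur)) cur <- 0L
  aa[pos] <- SAFE_AA[((cur + shift - 1L) %% length(SAFE_AA)) + 1L]
  paste0(aa, collapse = "")
}

# One ortholog family: members inside each block's target clade share the
# base block; each member outside gets its own species variant. A peptide's
# taxon set in the panel index then has LCA exactly the block's target.
ortholog_family <- function(prefix, protein_class, members, level_plan,
                            tree) {
  base <- vapply(level_plan, function(x) random_block(), character(1))
  seqs <- vapply(members, function(member) {
    paste0(vapply(seq_along(level_plan), function(b) {
      if (taxon_is_descendant(tree, member, level_plan[[b]]))
        base[[b]]
      else
        block_variant(base[[b]], match(member, members))
    }, character(1)), collapse = "")
  }, character(1))
  data.frame(accession = paste0(prefix, "_", TAXON_CODES[members], "_SYN"),
             taxon = members, protein_class = protein_class,
             sequence = unname(seqs), signal_peptide_end = NA_integer_,
             stringsAsFactors = FALSE)
}

random_protein <- function(accession, taxon, protein_class,
                           n_blocks = 10L) {
  data.frame(accession = accession, taxon = taxon,
             protein_class = protein_class,
             sequence = paste0(vapply(seq_len(n_blocks),
                                      function(i) random_block(),
                                      character(1)), collapse = ""),
             signal_peptide_end = NA_integer_, stringsAsFactors = FALSE)
}

ORAL_BACTERIA <- c("Streptococcus mitis", "Streptococcus sanguinis",
                   "Actinomyces oris", "Tannerella forsythia",
                   "Porphyromonas gingivalis", "Fusobacterium nucleatum",
                   "Rothia dentocariosa", "Veillonella parvula",
                   "Neisseria flavescens", "Treponema denticola")

#' Synthetic calculus reference metaproteome panel
#'
#' Builds, deterministically and entirely in code, the reference panel the
#' simulator and pipeline tests run against: the bundled
#' beta-lactoglobulin ortholog set plus synthetic ortholog families for the
#' other dietary proteins recoverable from calculus (equine BLG1, the four
#' caseins, alpha-lactalbumin, milk lysozyme, hemoglobin, serum albumin),
#' 40 oral-microbiome proteins across ten common oral bacteria, 10 human
#' immune proteins, and lab/environmental contaminants (keratins, trypsin,
#' collagens). Dietary families are built from conservation blocks so that
#' peptides exist with least-common-ancestor at every taxonomic level the
#' analysis reports (species through infraorder). All non-BLG sequences are
#' synthetic: only their shared-vs-variant block structure, not their
#' residue composition, carries meaning.
#'
#' @param tree a [taxonomy_tree()]; defaults to [default_taxonomy()].
#' @param include_blg include the bundled BLG ortholog fixture
#'   (default `TRUE`).
#' @return A `protein_panel` data frame.
#' @export
synthetic_metaproteome_panel <- function(tree = default_taxonomy(),
                                         include_blg = TRUE) {
  with_seed(104729L, {
    fams <- list(
      ortholog_family("BLG1", "whey", EQUIDS,
                      c(rep("Equus", 8L), "Equus caballus", "Equus asinus"),
                      tree),
      ortholog_family("BCAS", "casein", c(RUMINANTS, EQUIDS),
                      c("Pecora", "Pecora", "Bovidae", "Bovidae", "Bovinae",
                        "Bos", "Caprinae", "Caprinae", "Equus", "Equus",
                        "Bos grunniens/mutus", "Ovis aries"), tree),
      ortholog_family("AS1C", "casein", RUMINANTS,
                      c("Pecora", "Bovidae", "Bovidae", "Bovinae",
                        "Caprinae", "Ovis aries", "Bos"), tree),
      ortholog_family("AS2C", "casein", c(RUMINANTS, EQUIDS),
                      c("Pecora", "Bovidae", "Bovinae", "Equus", "Equus",
                        "Caprinae", "Bos grunniens/mutus"), tree),
      ortholog_family("KCAS", "casein", RUMINANTS,
                      c("Pecora", "Bovidae", "Bovidae", "Bovinae",
                        "Bovinae", "Caprinae", "Bos"), tree),
      ortholog_family("LALBA", "whey", c(RUMINANTS, EQUIDS),
                      c("Pecora", "Bovidae", "Equus", "Equus", "Bovinae",
                        "Caprinae"), tree),
      ortholog_family("LYZM", "whey", EQUIDS,
                      c("Equus", "Equus", "Equus", "Equus caballus",
                        "Equus asinus"), tree),
      ortholog_family("HBB", "blood_tissue", RUMINANTS,
                      c("Pecora", "Pecora", "Bovidae", "Bovidae", "Bovinae",
                        "Caprinae"), tree),
      ortholog_family("ALB", "blood_tissue", c(RUMINANTS, EQUIDS),
                      c("Equus", "Equus", "Equus", "Pecora", "Bovidae",
                        "Bovinae", "Caprinae"), tree))
    micro <- do.call(rbind, lapply(1:40, function(i)
      random_protein(sprintf("OMB%03d", i),
                     ORAL_BACTERIA[((i - 1L) %% length(ORAL_BACTERIA)) + 1L],
                     "microbiome")))
    immune <- do.call(rbind, lapply(1:10, function(i)
      random_protein(sprintf("IMM%03d", i), "Homo sapiens", "immune")))
    lab <- rbind(
      do.call(rbind, lapply(1:4, function(i)
        random_protein(sprintf("LABK%02d", i), "Homo sapiens",
                       "lab_contaminant", n_blocks = 14L))),
      random_protein("LABT01", "Sus scrofa", "lab_contaminant"))
    env <- do.call(rbind, lapply(1:5, function(i)
      random_protein(sprintf("ENVC%02d", i),
                     c("Bos taurus", "Homo sapiens", "Ovis aries",
                       "Bos taurus", "Homo sapiens")[i],
                     "env_contaminant", n_blocks = 16L)))
    panel <- rbind(do.call(rbind, fams), micro, immune, lab, env)
    if (include_blg) panel <- rbind(bundled_blg_panel(), panel)
    rownames(panel) <- NULL
    validate_panel(panel)
  })
}
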