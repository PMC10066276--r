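# shared fixtures, built once per test run

tax <- default_taxonomy()
blg <- bundled_blg_panel()
panel <- synthetic_metaproteome_panel(tax)
pep_index <- build_peptide_index(panel, tax)

blg_record <- function(taxon) blg[blg$taxon == taxon, , drop = FALSE]

terminal_peptide <- function(taxon) {
  dg <- tryptic_digest(blg_record(taxon), max_missed_cleavages = 0L)
  dg$peptide[nrow(dg)]
}

# minimal PSM data frame builder
psm_df <- function(peptide, accession = "ACC1", sample_id = "S1",
                   e_value = 1e-4, prev_aa = "K", next_aa = "G",
                   spectrum_id = NULL, mods = "") {
  n <- max(length(peptide), length(accession), length(e_value))
  data.frame(
    sample_id = rep_len(sample_id, n),
    spectrum_id = if (is.null(spectrum_id)) sprintf("sp%03d", seq_len(n))
                  else rep_len(spectrum_id, n),
    protein_accession = rep_len(accession, n),
    peptide = rep_len(peptide, n),
    prev_aa = rep_len(prev_aa, n),
    next_aa = rep_len(next_aa, n),
    e_value = rep_len(e_value, n),
    ion_score = rep_len(50, n),
    mods = rep_len(mods, n),
    stringsAsFactors = FALSE)
}

# brute-force diagnosticity oracle: scan every other taxon's digests for
# the collapsed peptide as a tryptic peptide (independent of the index)
brute_force_diagnostic <- function(some_panel, taxon, max_missed = 1L,
                                   min_len = 6L, max_len = 30L) {
  digest_keys <- function(rows) {
    unique(unlist(lapply(seq_len(nrow(rows)), function(i) {
      dg <- tryptic_digest(rows[i, , drop = FALSE],
                           max_missed_cleavages = max_missed)
      keep <- nchar(dg$peptide) >= min_len & nchar(dg$peptide) <= max_len
      collapse_il(dg$peptide[keep])
    })))
  }
  own <- digest_keys(some_panel[some_panel$taxon == taxon, , drop = FALSE])
  other <- digest_keys(some_panel[some_panel$taxon != taxon, , drop = FALSE])
  setdiff(own, other)
}

# brute-force LCA over all pairs: repeatedly reduce with pairwise LCA
brute_force_lca <- function(tree, taxa) {
  pair_lca <- function(a, b) {
    pa <- taxon_ancestors(tree, a)
    for (x in pa) if (taxon_is_descendant(tree, b, x)) return(x)
    tree$root
  }
  Reduce(pair_lca, taxa)
}
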