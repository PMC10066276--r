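# paleocalc

Dietary protein inference from ancient dental calculus metaproteomes.

Ancient dental calculus traps proteins from the oral microbiome, the host
immune system, and — crucially for archaeology — food. Shotgun proteomics
of calculus can therefore reveal who consumed milk, meat, or blood from
which animals. The catch is taxonomy: most tryptic peptides are shared
across related species, so every dietary claim rests on (i) knowing which
peptides are truly species-diagnostic against a reference panel, and
(ii) honestly demoting every shared peptide to the *least common ancestor*
(LCA) of everything it matches. The textbook case is beta-lactoglobulin
(BLG): the yak paralog BLG-E differs from the cattle sequence by a single
amino acid, located in the final (C-terminal, 14-residue) tryptic peptide —
recover that one peptide and you can claim yak milk; recover anything else
from BLG and you can only claim *Bos*, Bovinae, Bovidae, or Pecora.

`paleocalc` implements the full inference chain as reusable, tested R
functions:

1. **Reference panel & digestion** — `read_panel_fasta()`,
   `tryptic_digest()` (cleave after K/R, never before P, configurable
   missed cleavages, mature-chain aware), `build_peptide_index()` with
   I/L collapse (isobaric residues are indistinguishable on the
   instrument), `diagnostic_peptides()`, `hamming()`, `global_identity()`.
2. **PSM filtration** — `filter_psms()`: drop peptide-spectrum matches
   with e-value above 0.01, then drop proteins supported by fewer than
   two distinct peptides (both thresholds configurable via
   `filter_params()`).
3. **Preservation QC** — `assess_preservation()`: the oral-signature
   screening (OSSD) score, 100 × (oral microbiome + immune proteins) /
   total OSSD proteins; a sample passes with score strictly above 45 and
   at least 10 OSSD proteins. `atomic_cn_ratio()` covers the collagen
   C/N radiocarbon-suitability window (2.9–3.6).
4. **Taxonomy assignment** — `assign_lca()` / `summarize_dietary()`:
   peptide → matched taxa → LCA; peptides are dietary evidence when their
   LCA falls at or below the genus *Equus* or the infraorder Pecora.
5. **Authentication** — `classify_cleavage()` / `tryptic_fraction()`:
   flanking-residue check that PSMs are fully tryptic, with the
   non-tryptic remainder broken down by protein class.
6. **Synthetic data** — `simulate_sample()` / `simulate_study()`: a seeded
   generator of PSM tables with configurable oral/immune/contaminant
   composition, dietary peptides drawn under exact-LCA constraints,
   log-uniform e-value noise and semi-tryptic truncations, plus a
   ground-truth ledger the pipeline never reads.
7. **Pipeline** — `run_pipeline()`: filtration → preservation gate →
   (passing samples only) authentication, LCA assignment, dietary
   summary; `render_proportions()` for stacked per-individual tables;
   a thin CLI in `inst/cli/paleocalc.R`.

## Worked example

```r
library(paleocalc)
tree <- default_taxonomy()
blg  <- bundled_blg_panel()          # 7 BLG orthologs, cattle P02754 etc.
idx  <- build_peptide_index(blg, tree)

diagnostic_peptides(idx, "Bos grunniens/mutus")
#> [1] "ALPMHLRLSFNPTQLEGQCHL" "LSFNPTQLEGQCHL"
```

Only the terminal BLG-E peptide (and its missed-cleavage extension) is
yak-diagnostic — every other BLG peptide is shared with relatives. It is
14 residues long and one substitution away from cattle, whose whole
sequence is 99.44 % identical:

```r
cow <- blg[blg$taxon == "Bos taurus", ]
yak <- blg[blg$taxon == "Bos grunniens/mutus", ]
term <- function(r) { d <- tryptic_digest(r, 0); d$peptide[nrow(d)] }
term(yak)                                      #> "LSFNPTQLEGQCHI"
hamming(term(cow), term(yak))                  #> 1
global_identity(cow$sequence, yak$sequence)    #> 99.44
```

A full synthetic cohort through the pipeline (eleven individuals, one
degraded, the rest mirroring a permafrost-preserved burial group):

```r
panel <- synthetic_metaproteome_panel(tree)
pidx  <- build_peptide_index(panel, tree)
study <- simulate_study(khorig_like_config(seed = 1),
                        panel = panel, tree = tree, index = pidx)
psms  <- do.call(rbind, lapply(study$samples, `[[`, "psms"))
report <- run_pipeline(psms, panel = panel, tree = tree, index = pidx)
report
#> pipeline_report: 11 sample(s), 10 passed preservation
#>    sample_id n_informative_peptides n_informative_psms n_milk_peptides ...
#> 6     HOR-27                     25                 52              23
```

Ten of eleven samples pass preservation (the degraded one is gated out of
dietary interpretation); eight of the ten passing samples carry dietary
evidence, seven of those eight include horse (Equus) milk, and two
individuals carry the yak-diagnostic BLG-E peptide. The richest sample
totals 23 informative milk peptides — 1 yak + 12 Equus + 2 Bovinae +
4 Bovidae + 4 Pecora:

```r
subset(report$summary$by_taxon,
       sample_id == "HOR-27" & food_class == "milk_whey")
#>    sample_id                 lca       rank food_class n_peptides n_psms ...
#> 18    HOR-27 Bos grunniens/mutus    species  milk_whey          1      2
#> 17    HOR-27               Equus      genus  milk_whey          8     16
#> 19    HOR-27              Pecora infraorder  milk_whey          2      5
```

## Notes on bundled data

All fixtures are small plain-text files under `inst/extdata/`. The BLG
panel (`blg_panel_synthetic.fasta`) is a reconstruction built offline:
cattle carries the canonical 162-residue mature BLG, yak differs from it
by exactly one residue in the terminal tryptic peptide, and the other
orthologs reproduce the documented pattern of increasing divergence with
phylogenetic distance; see the methods vignette for what this does and
does not validate. The non-BLG dietary families, the microbiome/immune/
contaminant proteins, and the default OSSD map are synthetic and generated
in code (`synthetic_metaproteome_panel()`).
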