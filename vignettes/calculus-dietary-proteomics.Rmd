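---
title: "Methods: dietary protein inference from dental calculus metaproteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary protein inference from dental calculus metaproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleocalc)
```

## The inference problem

A calculus metaproteome is a bag of peptide-spectrum matches (PSMs) from a
mixture of oral bacteria, host immune proteins, laboratory and
environmental contaminants, and — rarely and precious — dietary proteins.
Three questions must be answered before any dietary claim:

1. *Is the sample authentically oral?* Degraded or contaminated samples
   produce spurious identifications; diet should not be interpreted in
   them at all.
2. *Is each peptide credible?* Search-engine matches carry e-values, and
   one-hit proteins are unreliable.
3. *How specific is each peptide, really?* A peptide present in several
   species' proteins can only support their least common ancestor (LCA),
   not any single species.

`paleocalc` encodes these as a gated chain:
filtration → preservation assessment → (passing samples only) LCA
assignment, authentication, dietary summary. The gate is deliberate: a
sample that fails preservation gets a report block saying "not assessed",
never a dietary table.

## Reference digestion and the peptide index

Trypsin cleaves C-terminal to K or R; following the standard Keil rule we
suppress cleavage when the next residue is proline. The digestion
contract is exact: at zero missed cleavages the peptides partition the
sequence; at $m$ missed cleavages the output additionally contains every
concatenation of up to $m+1$ adjacent base peptides, each carrying its
true flanking residues. Secreted proteins (all milk proteins) are
digested from the mature chain when a signal-peptide boundary is
annotated, since that is what the instrument can observe.

The peptide index maps every digestion product to the set of panel taxa
containing it. Keys are I/L-collapsed: leucine and isoleucine are
isobaric and cannot be distinguished by the mass spectrometer, so treating
them as distinct would manufacture false diagnosticity. Raw sequences are
preserved in the records; only matching is collapsed. A peptide is
*diagnostic* for a taxon when its taxon set is that singleton — the
package verifies this definition against a brute-force scan of all other
taxa's digests in its test suite.

Index defaults: up to 1 missed cleavage (typical search settings allow
one or two; one keeps the index compact while still containing the
biologically important extensions), peptide length 6–30 residues (the
usual detectability window for tryptic searches). Both are configurable;
nothing downstream assumes the defaults.

## Filtration

Two steps, in a fixed order: PSMs with e-value strictly above
`max_e_value` (default 0.01) are removed first; then every PSM of a
protein whose surviving support falls below
`min_unique_psms_per_protein` (default 2) is removed. Support must be
counted over credible PSMs only, which is why the e-value step runs
first. The boundary is literal: an e-value of exactly 0.01 survives.

"Unique PSMs" is an ambiguous phrase in the field; we interpret it as
*distinct I/L-collapsed peptide sequences per protein* (modifications and
spectra ignored), and also provide the distinct-spectrum counter
(`uniqueness = "spectrum"`) for users who read it the other way. The
sequence reading is the stricter and therefore the safer default.
Filtration is idempotent, order-independent, and monotone in both
parameters; these are tested as properties, not examples.

## Preservation scoring (OSSD)

Identified proteins (protein-level — an accession counts once no matter
how many PSMs support it) are looked up in an Oral Signature Screening
Database mapping accessions to one of four categories: oral microbiome,
immune, laboratory contaminant, environmental contaminant. The score is

$$\mathrm{score} = 100 \times
  \frac{n_\text{oral microbiome} + n_\text{immune}}{n_\text{OSSD total}}$$

and a sample passes when score > 45 (strictly) and at least 10 OSSD
proteins were identified. Both phrasings of the threshold in the
literature ("above 45", "> 45") agree on strictness, so a score of
exactly 45 fails. We read "at least ten total proteins" as ten *OSSD*
proteins — the score's own denominator — rather than ten identified
proteins of any kind; the alternative reading would let a sample pass on
a denominator of three, which defeats the statistic's purpose. With no
OSSD proteins at all the score is undefined (`NA`), the sample fails, and
the result carries an explicit flag.

The bundled OSSD map is a 60-accession illustrative default matching the
synthetic panel; analyses of real data must supply the curated screening
list as a TSV (`read_ossd_map()`).

The collagen quality check for radiocarbon dating converts elemental mass
percentages to the atomic C/N ratio using atomic masses 12.011 and
14.007; the accepted window 2.9–3.6 is inclusive at both ends ("outside
the range" excludes only strict outsiders).

## LCA assignment and dietary informativeness

A peptide's matched taxa are reduced to their LCA by walking parent links
in the taxonomy. The bundled tree spans the pecoran ruminants (Bovidae:
Bovinae with *Bos* — cattle, zebu, yak — and bison; Caprinae with sheep
and goat; plus Cervidae), the equids (joined to the ruminants only at the
mammalian root), host, swine, and common oral bacteria. Cervidae and
bison matter structurally: without a second family under Pecora and a
second lineage under Bovinae, no set of taxa could have *exactly* Pecora
or Bovinae as its LCA, yet those are precisely the levels at which many
real milk peptides resolve (they match deer or bison orthologs in public
databases too).

A peptide is *taxonomically informative for diet* when its LCA lies at or
below the genus *Equus*, or at or below the infraorder Pecora. We apply
"at or below" on the Equus side as well: a peptide private to
*Equus caballus* is horse-milk evidence a fortiori. Everything broader
(e.g. a peptide shared by cattle and horse, LCA Mammalia) is retained in
assignment output but excluded from dietary proportions.

Food class (milk whey, milk casein, blood/tissue) is inherited from the
matched reference records. If a peptide's matches span conflicting
classes — say a milk protein and a contaminant collagen — the peptide is
conservatively classed "other" and excluded from dietary counts. This
mirrors the manual curation step in which ambiguous BLAST hits are
discarded, and it is a deliberate design decision: the package prefers
losing a true dietary peptide to counting a contaminant.

Hybrids (yak–cattle crosses and similar) are not tree nodes; sequences
attributed to hybrids should be annotated to the genus *Bos*, which is
where any hybrid-shared peptide resolves anyway.

## Tryptic authentication

For every PSM the flanking residues decide whether each terminus is
trypsin-consistent (preceding residue K/R and peptide not starting with
P, or a protein terminus; symmetrically on the C side). Protein termini
count as valid boundaries — the standard convention — and the proline
exception applies on both sides, exactly matching the digester, a
cross-module consistency the tests enforce on every digestion product.
`tryptic_fraction()` reports the fully-tryptic fraction among
classifiable PSMs and tabulates the remainder by protein class; in
authentic material the non-tryptic tail should be dominated by
contaminant collagens and keratins.

## The synthetic generator: what it emulates, and what it does not

`simulate_sample()` assembles a PSM table from four components:

* **Background proteins** at regime-dependent counts
  (`well_preserved`: 25–40 oral microbiome, 6–10 immune, 3–5 each
  contaminant class; `degraded`: 1–3 oral, 0–2 immune, 4–5 each
  contaminant). Each protein is supported by 2–4 distinct peptides at
  1–3 PSMs each. The regimes are calibrated so that a well-preserved
  sample passes the OSSD rule with probability approaching one as counts
  grow, and a degraded sample fails it — which is the property the tests
  assert, not a tuned coincidence: 31–50 oral+immune proteins over 37–60
  OSSD total sits far above the 45 % line, 1–5 over 9–15 far below.
* **Dietary peptides** drawn from the reference digest under an
  *exact-LCA constraint*: a request for two Bovidae-level casein peptides
  draws peptides whose matched-taxon LCA is exactly Bovidae. Flanking
  residues come from the true digest context. Draws are clustered onto
  as few proteins as possible (a deterministic max-coverage planner with
  a repair pass) so that every dietary protein carries at least two
  distinct peptides and survives filtration; a request that cannot be
  satisfied fails loudly rather than silently losing a taxon.
* **Noise PSMs** with log10 e-value uniform on [−2, 0] (signal:
  [−8, −2.2]). Log-uniform is a deliberate simplification: only
  threshold behaviour at 0.01 matters downstream, not the shape of a
  search engine's score distribution.
* **Semi-tryptic truncations** applied, by default, only to background
  PSMs — matching the empirical pattern that non-tryptic peptides in real
  calculus are overwhelmingly contaminant collagen/keratin — and leaving
  ground-truth dietary peptides intact so ledger recovery stays exact.
  Deamidation (default rate 0.3 per N/Q site, an "ancient-like" level)
  and oxidation flags are recorded for realism; no analysis stage
  consumes them yet.

Every sample is deterministic given `(seed, sample_index)`; the
ground-truth ledger is written alongside but never read by any analysis
function.

The bundled cohort preset (`khorig_like_config()`) encodes eleven
individuals: ten well-preserved and one degraded; eight of the ten
passing samples with dietary evidence; seven of those eight with horse
milk; two with a yak-diagnostic peptide; and one individual whose milk
composition is exactly 1 yak + 12 Equus + 2 Bovinae + 4 Bovidae +
4 Pecora = 23 informative milk peptides. These are the study conditions
the package is built to reproduce, fixed in the preset and not adjusted
thereafter.

**What passing tests show:** the chain is algebraically correct — filters
behave as specified, LCAs equal a brute-force oracle, planted taxa are
recovered exactly with no spurious species-level calls across seeds, and
byte-identical reruns. **What they do not show:** performance on real
spectra. The generator does not model spectra, intensities, retention
times, search-engine score correlation, protein inference ambiguity,
damage-induced misidentification, or database incompleteness. A real
analysis substitutes the bundled panel and OSSD map with curated ones and
keeps the code path identical.

## The bundled BLG panel

The seven-ortholog beta-lactoglobulin fixture is a reconstruction built
without network access, and is labelled synthetic accordingly. The
cattle record carries the canonical 162-residue mature BLG (with the
16-residue signal peptide annotated); the yak BLG-E record differs from
cattle by exactly one substitution, placed in the terminal tryptic
peptide; sheep/goat/deer/bison/zebu orthologs carry designed variants
reproducing the qualitative divergence pattern (sheep differs from cattle
at three terminal-peptide positions, yak at one). Consequences that
depend only on this structure — the 14-residue terminal peptide, the
single-residue yak diagnostic, >99 % cattle–yak identity, the ordering
hamming(sheep, cattle) > hamming(yak, cattle) — are computed by the
package and asserted in tests. Residue-level claims beyond that structure
(e.g. *which* position varies) are properties of the reconstruction, not
of the database records, and nothing in the package depends on them.

The non-BLG dietary families (equine BLG1, four caseins,
alpha-lactalbumin, milk lysozyme, hemoglobin, serum albumin) are
synthetic ortholog families generated from conservation blocks: members
inside a block's target clade share the block, members outside carry
single-substitution variants, so peptides exist with LCA at every level
the analysis reports. Only this shared-vs-variant structure is
meaningful; the residue content is random over an alphabet that excludes
K/R (cleavage), P (Keil rule), I (collapse ambiguity) and C inside
blocks.

## Numerical and degenerate-input choices

* Global identity is computed from a Needleman–Wunsch alignment
  (BLOSUM62, gap open 10, extend 0.5) as matches over alignment columns
  × 100; symmetric by construction.
* Empty sequence → empty digest; empty PSM table → empty (not failing)
  filtration; zero classifiable PSMs → `NA` tryptic fraction with a
  flag; zero OSSD proteins → `NA` score, failed, flagged; empty taxon
  set → `NA` LCA.
* Dietary proportions are reported over informative dietary PSMs (and,
  separately, peptides) per sample; they sum to 1 within 1e-9 whenever
  any exist.
* Ties in the simulator's accession planner break alphabetically, and
  per-sample RNG streams derive from the master seed by a fixed integer
  recurrence kept below 2^31, so studies are reproducible byte for byte.

## Problem sizes

The shipped tests run the full chain on one 11-sample cohort, twenty
2-sample studies for ledger recovery, a 4-sample (~2,600 PSM) study for
the semi-tryptic rate, and property loops of 10–50 random cases per
invariant — sizes chosen to exercise every code path and keep the suite
comfortably under a coffee break on a single core. All generators scale
by configuration if heavier validation is wanted.

## Known limitations

* LCA specificity is relative to the panel: a peptide "diagnostic" here
  may be shared with a species the panel lacks. This is inherent to the
  method (BLAST-based curation has the same property) and is why panel
  composition is a first-class input.
* The preservation score is a sample-level screen; it cannot
  authenticate individual peptides.
* Deamidation is recorded but not yet used as an authentication metric.
* The semi-tryptic fraction is classification arithmetic only; the
  package does not re-search spectra under semi-tryptic settings.
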