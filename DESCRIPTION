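Package: paleocalc
Title: Dietary Protein Inference from Ancient Dental Calculus Metaproteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paleoproteomic analysis of peptide-spectrum matches
    (PSMs) recovered from ancient dental calculus. Implements in-silico
    tryptic digestion of an annotated reference protein panel, discovery of
    taxon-diagnostic peptides (e.g. the single-residue beta-lactoglobulin
    BLG-E variant that separates yak from cattle), PSM filtration by e-value
    and protein support, oral-signature preservation scoring (OSSD),
    peptide-to-taxon least-common-ancestor assignment, tryptic-cleavage
    authentication, and per-individual dietary summaries. A seeded synthetic
    PSM generator emulates calculus metaproteomes with configurable
    oral-microbiome, immune, contaminant, and dietary composition so the
    whole chain is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
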