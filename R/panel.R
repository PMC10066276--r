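PROTEIN_CLASSES <- c("whey", "casein", "blood_tissue", "immune",
                     "microbiome", "lab_contaminant", "env_contaminant",
                     "other")

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  need <- c("accession", "taxon", "protein_class", "sequence",
            "signal_peptide_end")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel missing column(s): ", paste(miss, collapse = ", "))
  bad <- !panel$protein_class %in% PROTEIN_CLASSES
  if (any(bad))
    stop("unknown protein_class: ",
         paste(unique(panel$protein_class[bad]), collapse = ", "))
  for (i in seq_len(nrow(panel))) {
    s <- panel$sequence[i]
    if (nchar(s) == 0L)
      stop("empty sequence for accession ", panel$accession[i])
    res <- strsplit(s, "")[[1L]]
    ill <- which(!res %in% AA_ALPHABET)
    if (length(ill))
      stop("illegal residue '", res[ill[1L]], "' at position ", ill[1L],
           " in accession ", panel$accession[i])
    spe <- panel$signal_peptide_end[i]
    if (!is.na(spe) && (spe < 0L || spe >= nchar(s)))
      stop("signal_peptide_end out of range for accession ",
           panel$accession[i])
  }
  class(panel) <- c("protein_panel", "data.frame")
  panel
}

# Biostrings drops invalid one-letter codes silently, so residues are
# checked against the raw file first to report accession and position
check_fasta_residues <- function(path) {
  lines <- readLines(path)
  acc <- NA_character_
  pos <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      acc <- strsplit(sub("^>", "", ln), "\\s+")[[1L]][1L]
      pos <- 0L
      next
    }
    res <- strsplit(toupper(gsub("\\s", "", ln)), "")[[1L]]
    bad <- which(!res %in% AA_ALPHABET)
    if (length(bad))
      stop("illegal residue '", res[bad[1L]], "' at position ",
           pos + bad[1L], " in accession ", acc)
    pos <- pos + length(res)
  }
  invisible(TRUE)
}

#' Read an annotated reference protein panel from FASTA
#'
#' The panel is the reference search space for peptide taxonomy: each entry
#' is an amino-acid sequence annotated with its source taxon and protein
#' class (whey, casein, blood/tissue, immune, microbiome, contaminant).
#' The accession is the first whitespace-delimited token of the FASTA
#' header and must appear in the annotation table.
#'
#' @param path path to a FASTA file of protein sequences.
#' @param annotations a data frame (or path to a TSV) with columns
#'   `accession`, `taxon`, `protein_class` and optionally
#'   `signal_peptide_end` (0-based index of the first mature residue).
#' @return A `protein_panel` data frame with columns `accession`, `taxon`,
#'   `protein_class`, `sequence`, `signal_peptide_end`, one row per FASTA
#'   entry in file order.
#' @seealso [bundled_blg_panel()] for the packaged beta-lactoglobulin set.
#' @export
read_panel_fasta <- function(path, annotations) {
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(annotations))
  if (!"signal_peptide_end" %in% names(annotations))
    annotations$signal_peptide_end <- NA_integer_
  check_fasta_residues(path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L)
    return(validate_panel(data.frame(
      accession = character(0), taxon = character(0),
      protein_class = character(0), sequence = character(0),
      signal_peptide_end = integer(0), stringsAsFactors = FALSE)))
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  miss <- setdiff(acc, annotations$accession)
  if (length(miss))
    stop("no annotation for accession(s): ", paste(miss, collapse = ", "))
  idx <- match(acc, annotations$accession)
  panel <- data.frame(
    accession = acc,
    taxon = annotations$taxon[idx],
    protein_class = annotations$protein_class[idx],
    sequence = toupper(as.character(seqs)),
    signal_peptide_end = as.integer(annotations$signal_peptide_end[idx]),
    stringsAsFactors = FALSE)
  rownames(panel) <- NULL
  validate_panel(panel)
}

#' Mature sequence of a panel record
#'
#' Strips the annotated signal peptide, if any. Milk proteins are secreted,
#' so the peptides observable in calculus come from the mature chain.
#'
#' @param record single-row `protein_panel` data frame.
#' @return amino-acid string.
#' @export
mature_sequence <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  s <- record$sequence
  spe <- record$signal_peptide_end
  if (!is.na(spe) && spe > 0L) substr(s, spe + 1L, nchar(s)) else s
}

#' Bundled beta-lactoglobulin reference panel
#'
#' Loads the packaged BLG ortholog set for cattle (accession P02754), zebu,
#' yak (BLG-E, accession L8J1Z0), bison, sheep, goat, and red deer, with the
#' standard 16-residue signal peptide annotated. Built offline, these
#' sequences are synthetic reconstructions of the database orthologs (see
#' the file `blg_panel_synthetic.fasta`): the cattle entry is the canonical
#' 162-residue mature BLG and the yak BLG-E entry differs from it by exactly
#' one residue in the final tryptic peptide, which is what makes that
#' 14-residue peptide yak-diagnostic; the remaining orthologs reproduce the
#' documented pattern of increasing divergence with phylogenetic distance.
#'
#' @return A `protein_panel` data frame of 7 whey-protein records.
#' @export
bundled_blg_panel <- function() {
  read_panel_fasta(
    system.file("extdata", "blg_panel_synthetic.fasta",
                package = "paleocalc", mustWork = TRUE),
    system.file("extdata", "blg_panel_annotations.tsv",
                package = "paleocalc", mustWork = TRUE))
}
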