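#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to lysine (K) or arginine (R),
#' except when the next residue is proline (the Keil rule). With
#' `max_missed_cleavages = 0` the peptides partition the digested sequence
#' exactly; with `m > 0` the output additionally contains every
#' concatenation of up to `m + 1` adjacent base peptides. Secreted proteins
#' are digested from their mature sequence when a signal peptide boundary is
#' annotated.
#'
#' @param sequence upper-case amino-acid string, or a single-row
#'   protein-panel data frame (see [read_panel_fasta()]).
#' @param max_missed_cleavages non-negative integer, number of internal
#'   uncleaved K/R sites allowed (default 1).
#' @param use_mature if `TRUE` (default) and a `signal_peptide_end`
#'   annotation is available, digest from that residue onward.
#' @param accession accession string recorded in the output (taken from the
#'   record when one is supplied).
#' @return A data frame with one row per peptide: `peptide`, `accession`,
#'   `start`, `end` (0-based half-open interval into the digested sequence),
#'   `missed_cleavages`, `prev_aa`, `next_aa` (flanking residues, `"-"` at a
#'   terminus).
#' @examples
#' tryptic_digest("AKRPGK", max_missed_cleavages = 0)$peptide  # "AK", "RPGK"
#' @export
tryptic_digest <- function(sequence, max_missed_cleavages = 1L,
                           use_mature = TRUE, accession = NA_character_) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    rec <- sequence
    accession <- rec$accession
    sequence <- rec$sequence
    if (use_mature && !is.null(rec$signal_peptide_end) &&
        !is.na(rec$signal_peptide_end) && rec$signal_peptide_end > 0L)
      sequence <- substr(sequence, rec$signal_peptide_end + 1L,
                         nchar(sequence))
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (max_missed_cleavages < 0L) stop("max_missed_cleavages must be >= 0")
  n <- nchar(sequence)
  empty <- data.frame(peptide = character(0), accession = character(0),
                      start = integer(0), end = integer(0),
                      missed_cleavages = integer(0),
                      prev_aa = character(0), next_aa = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  # cleavage after position i (1-based) iff aa[i] in K/R and aa[i+1] != P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)  # 0-based block ends
  bounds <- unique(bounds)
  nb <- length(bounds) - 1L  # number of base peptides
  rows <- vector("list", 0L)
  for (i in seq_len(nb)) {
    for (m in 0:max_missed_cleavages) {
      j <- i + m
      if (j > nb) break
      s <- bounds[i]          # 0-based start
      e <- bounds[j + 1L]     # 0-based end (exclusive)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = substr(sequence, s + 1L, e),
        accession = accession,
        start = s, end = e, missed_cleavages = m,
        prev_aa = if (s == 0L) "-" else aa[s],
        next_aa = if (e == n) "-" else aa[e + 1L],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collapse isoleucine to leucine
#'
#' I and L are isobaric and indistinguishable by tandem mass spectrometry;
#' peptide identity throughout the package is therefore defined on the
#' I/L-collapsed string.
#'
#' @param x character vector of peptide sequences.
#' @return character vector with every `I` replaced by `L`.
#' @export
collapse_il <- function(x) gsub("I", "L", x, fixed = TRUE)

#' Hamming distance between equal-length peptides
#'
#' @param a,b equal-length amino-acid strings.
#' @return integer count of differing positions.
#' @export
hamming <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  if (nchar(a) != nchar(b))
    stop("hamming distance requires equal lengths (", nchar(a), " vs ",
         nchar(b), ")")
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Global alignment percent identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) via
#' [Biostrings::pairwiseAlignment()]; identity is matches divided by
#' alignment length (gap columns included), times 100. Symmetric in its
#' arguments.
#'
#' @param a,b non-empty amino-acid strings.
#' @return percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  100 * sum(pa == sa & pa != "-") / length(pa)
}
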