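#' Classify the tryptic status of PSMs from their flanking residues
#'
#' A peptide terminus is trypsin-consistent when the residue preceding the
#' peptide is K or R and the peptide does not start with proline (N side),
#' or the peptide ends in K/R and is not followed by proline (C side); a
#' protein terminus counts as a valid boundary on either side. The class is
#' decided by which sides pass: `fully_tryptic`, `semi_tryptic_nterm`
#' (N side fails), `semi_tryptic_cterm` (C side fails), `non_tryptic`
#' (both fail), or `unknown` when flanking information is missing.
#'
#' @param psms PSM data frame with `peptide`, `prev_aa`, `next_aa`
#'   (`"-"` denotes a protein terminus).
#' @return character vector of classes, one per PSM.
#' @export
classify_cleavage <- function(psms) {
  prev <- psms$prev_aa
  nxt <- psms$next_aa
  pep <- psms$peptide
  first <- substr(pep, 1L, 1L)
  last <- substr(pep, nchar(pep), nchar(pep))
  unknown <- is.na(prev) | is.na(nxt) | prev == "" | nxt == ""
  n_ok <- prev == "-" | (prev %in% c("K", "R") & first != "P")
  c_ok <- nxt == "-" | (last %in% c("K", "R") & nxt != "P")
  out <- ifelse(n_ok & c_ok, "fully_tryptic",
                ifelse(!n_ok & c_ok, "semi_tryptic_nterm",
                       ifelse(n_ok & !c_ok, "semi_tryptic_cterm",
                              "non_tryptic")))
  out[unknown] <- "unknown"
  out
}

#' Fraction of fully tryptic PSMs, with a contaminant breakdown
#'
#' The authentication cross-check: in authentic, well-preserved material
#' the large majority of PSMs should be fully tryptic, and the non-tryptic
#' remainder should be dominated by contaminant proteins (collagens,
#' keratins). Computes the fully-tryptic fraction among classifiable PSMs
#' and tabulates the rest by protein class.
#'
#' @param psms PSM data frame.
#' @param panel optional `protein_panel` used to map accessions to protein
#'   classes for the breakdown; unknown accessions are class `"other"`.
#' @return list with `fraction` (`NA` and a flag when nothing is
#'   classifiable), `n_classifiable`, `class_counts` (tryptic-status
#'   table), and `non_tryptic_by_class`.
#' @export
tryptic_fraction <- function(psms, panel = NULL) {
  cl <- classify_cleavage(psms)
  known <- cl != "unknown"
  n <- sum(known)
  if (n == 0L)
    return(list(fraction = NA_real_, n_classifiable = 0L,
                class_counts = table(cl),
                non_tryptic_by_class = table(character(0)),
                flag = "no classifiable PSMs"))
  frac <- sum(cl == "fully_tryptic") / n
  nt <- which(known & cl != "fully_tryptic")
  pcls <- if (!is.null(panel)) {
    m <- stats::setNames(panel$protein_class, panel$accession)
    cls <- m[psms$protein_accession[nt]]
    cls[is.na(cls)] <- "other"
    cls
  } else rep("other", length(nt))
  list(fraction = frac, n_classifiable = n, class_counts = table(cl),
       non_tryptic_by_class = table(pcls), flag = NA_character_)
}
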