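#' Build a peptide-to-taxon index from a reference panel
#'
#' Digests every panel record in silico and indexes the resulting peptides
#' by the set of taxa whose proteins contain them. Keys are I/L-collapsed
#' (isobaric residues are indistinguishable by the instrument); the raw
#' sequences remain available in the panel records. The index is the
#' substrate of both diagnosticity queries and least-common-ancestor
#' assignment, and embodies the "which species match this exact peptide"
#' check otherwise done by hand with BLASTp.
#'
#' @param panel a `protein_panel` data frame (see [read_panel_fasta()]).
#' @param tree a [taxonomy_tree()] covering every panel taxon.
#' @param max_missed_cleavages missed cleavages allowed during digestion
#'   (default 1).
#' @param min_length,max_length peptide length bounds for indexing
#'   (defaults 6 and 30, the usual detectability window).
#' @param use_mature digest mature sequences where a signal peptide is
#'   annotated (default `TRUE`).
#' @return An object of class `peptide_index`: list with `taxa` (named list
#'   mapping collapsed peptide -> character vector of taxa), `accessions`
#'   (collapsed peptide -> accessions containing it), `classes` (collapsed
#'   peptide -> protein classes of those records), and `params`.
#' @export
build_peptide_index <- function(panel, tree, max_missed_cleavages = 1L,
                                min_length = 6L, max_length = 30L,
                                use_mature = TRUE) {
  panel <- validate_panel(as.data.frame(panel))
  if (nrow(panel) == 0L) stop("panel is empty")
  unknown <- setdiff(unique(panel$taxon), tree$nodes)
  if (length(unknown))
    stop("panel taxon absent from taxonomy tree: ",
         paste(unknown, collapse = ", "))
  taxa <- list(); accs <- list(); cls <- list()
  for (i in seq_len(nrow(panel))) {
    dg <- tryptic_digest(panel[i, , drop = FALSE],
                         max_missed_cleavages = max_missed_cleavages,
                         use_mature = use_mature)
    keep <- nchar(dg$peptide) >= min_length & nchar(dg$peptide) <= max_length
    keys <- unique(collapse_il(dg$peptide[keep]))
    for (k in keys) {
      taxa[[k]] <- union(taxa[[k]], panel$taxon[i])
      accs[[k]] <- union(accs[[k]], panel$accession[i])
      cls[[k]]  <- union(cls[[k]], panel$protein_class[i])
    }
  }
  structure(list(taxa = taxa, accessions = accs, classes = cls,
                 params = list(max_missed_cleavages = max_missed_cleavages,
                               min_length = min_length,
                               max_length = max_length,
                               use_mature = use_mature)),
            class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat("peptide_index:", length(x$taxa), "peptides,",
      length(unique(unlist(x$taxa))), "taxa\n")
  invisible(x)
}

#' Taxon-diagnostic peptides
#'
#' Returns the indexed peptides found in exactly one taxon: the peptides
#' whose recovery in a sample supports a species/taxon-specific claim (for
#' yak, this is the terminal BLG-E peptide).
#'
#' @param index a [build_peptide_index()] result.
#' @param taxon taxon name present in the index's panel.
#' @param tree optional [taxonomy_tree()]; when supplied, `taxon` is
#'   validated against it.
#' @return character vector of I/L-collapsed peptide strings.
#' @export
diagnostic_peptides <- function(index, taxon, tree = NULL) {
  stopifnot(inherits(index, "peptide_index"))
  known <- unique(unlist(index$taxa, use.names = FALSE))
  if (!is.null(tree) && !taxon %in% tree$nodes)
    stop("unknown taxon: ", taxon)
  if (is.null(tree) && !taxon %in% known)
    stop("unknown taxon: ", taxon)
  keys <- names(index$taxa)
  keys[vapply(index$taxa, function(s) length(s) == 1L && s == taxon,
              logical(1))]
}
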