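PSM_COLUMNS <- c("sample_id", "spectrum_id", "protein_accession", "peptide",
                 "prev_aa", "next_aa", "e_value", "ion_score", "mods")

#' Read a peptide-spectrum-match (PSM) table
#'
#' One row per PSM, the tab-separated dialect emulating a search-engine
#' export: `sample_id`, `spectrum_id`, `protein_accession`, `peptide`,
#' `prev_aa`, `next_aa` (flanking residues, `"-"` at a protein terminus),
#' `e_value`, `ion_score`, `mods` (semicolon-joined `position:name`, e.g.
#' `"3:deamidated"`; empty for none).
#'
#' @param path path to the TSV file.
#' @return data frame of PSMs with numeric `e_value` and `ion_score`.
#' @export
read_psm_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(PSM_COLUMNS, names(df))
  if (length(miss))
    stop("PSM table missing required column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, PSM_COLUMNS]
  for (col in c("e_value", "ion_score")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop("cannot parse ", col, " at line ", bad[1L] + 1L, ": '",
           df[[col]][bad[1L]], "'")
    df[[col]] <- v
  }
  if (any(!is.na(df$e_value) & df$e_value <= 0))
    stop("e_value must be positive (line ",
         which(df$e_value <= 0)[1L] + 1L, ")")
  df$mods[is.na(df$mods)] <- ""
  df
}

#' Write a PSM table in the package's TSV dialect
#' @param psms PSM data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms[, PSM_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Count distinct peptides per protein
#'
#' Peptide uniqueness is defined on the I/L-collapsed sequence, ignoring
#' modifications and spectra: two PSMs of the same (collapsed) peptide on
#' one protein count once.
#'
#' @param psms PSM data frame.
#' @return named integer vector, accession -> distinct peptide count.
#' @export
unique_peptides_per_protein <- function(psms) {
  if (nrow(psms) == 0L) return(stats::setNames(integer(0), character(0)))
  key <- collapse_il(psms$peptide)
  tab <- tapply(key, psms$protein_accession,
                function(x) length(unique(x)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Count distinct spectra per protein
#'
#' The alternative reading of "unique PSMs": distinct spectrum identifiers
#' supporting each protein.
#'
#' @param psms PSM data frame.
#' @return named integer vector, accession -> distinct spectrum count.
#' @export
unique_spectra_per_protein <- function(psms) {
  if (nrow(psms) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- tapply(psms$spectrum_id, psms$protein_accession,
                function(x) length(unique(x)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Filtration parameters for PSM tables
#'
#' @param max_e_value PSMs with an e-value strictly above this are removed
#'   (default 0.01; a PSM at exactly the threshold is retained).
#' @param min_unique_psms_per_protein proteins whose surviving distinct
#'   peptide count falls below this lose all their PSMs (default 2).
#' @param uniqueness `"sequence"` (default: distinct collapsed peptides) or
#'   `"spectrum"` (distinct spectrum ids).
#' @return a `filter_params` list.
#' @export
filter_params <- function(max_e_value = 0.01,
                          min_unique_psms_per_protein = 2L,
                          uniqueness = c("sequence", "spectrum")) {
  stopifnot(max_e_value > 0, min_unique_psms_per_protein >= 1L)
  structure(list(max_e_value = max_e_value,
                 min_unique_psms_per_protein =
                   as.integer(min_unique_psms_per_protein),
                 uniqueness = match.arg(uniqueness)),
            class = "filter_params")
}

#' Filter PSMs by e-value and protein support
#'
#' Two-step filtration: first remove PSMs whose e-value is strictly above
#' `max_e_value`, then remove every PSM of proteins supported by fewer than
#' `min_unique_psms_per_protein` distinct peptides among the survivors.
#' Support is counted over credible (e-value-passing) PSMs only, which is
#' why the e-value step runs first. Row order is preserved; the output is a
#' subset of the input, so the operation is idempotent.
#'
#' @param psms PSM data frame.
#' @param params a [filter_params()] list.
#' @return filtered PSM data frame.
#' @export
filter_psms <- function(psms, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  if (nrow(psms) == 0L) return(psms)
  keep <- psms$e_value <= params$max_e_value
  out <- psms[keep, , drop = FALSE]
  counts <- if (params$uniqueness == "sequence")
    unique_peptides_per_protein(out) else unique_spectra_per_protein(out)
  ok <- names(counts)[counts >= params$min_unique_psms_per_protein]
  out <- out[out$protein_accession %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}
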