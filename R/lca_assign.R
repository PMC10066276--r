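food_class_of <- function(classes) {
  if (length(classes) == 1L && classes %in% names(FOOD_CLASSES))
    FOOD_CLASSES[[classes]] else "other"
}

#' Assign a peptide its least common taxonomic group
#'
#' Looks the (I/L-collapsed) peptide up in the reference index and reduces
#' the matched taxa to their least common ancestor in the taxonomy — the
#' programmatic equivalent of checking every BLASTp hit for a sequence and
#' reading off the narrowest shared taxonomic group. A peptide is
#' taxonomically informative for diet when its LCA lies at or below the
#' genus Equus, or at or below the infraorder Pecora; matches that resolve
#' only above those clades (e.g. a peptide shared by cattle and horse) are
#' retained but flagged uninformative. The food class is inherited from the
#' matched reference records; a peptide whose matches span conflicting
#' protein classes (e.g. a milk protein and a contaminant) is conservatively
#' classed `"other"` and thereby excluded from dietary counts.
#'
#' @param peptide amino-acid string (raw; collapsed internally).
#' @param index a [build_peptide_index()] result.
#' @param tree a [taxonomy_tree()] covering the indexed taxa.
#' @return list with `peptide` (collapsed key), `matched_taxa`, `lca`
#'   (`"unassigned"` when the peptide is absent from the index), `rank`,
#'   `informative` (logical), `food_class`.
#' @export
assign_lca <- function(peptide, index, tree) {
  key <- collapse_il(peptide)
  taxa <- index$taxa[[key]]
  if (is.null(taxa))
    return(list(peptide = key, matched_taxa = character(0),
                lca = "unassigned", rank = NA_character_,
                informative = FALSE, food_class = "other"))
  lca <- taxon_lca(tree, sort(taxa))
  informative <- taxon_is_descendant(tree, lca, "Equus") ||
    taxon_is_descendant(tree, lca, "Pecora")
  list(peptide = key, matched_taxa = sort(taxa), lca = lca,
       rank = unname(tree$rank[[lca]]), informative = informative,
       food_class = food_class_of(index$classes[[key]]))
}

#' Assign LCAs for every distinct peptide in a PSM table
#'
#' @param psms PSM data frame (normally already filtered).
#' @param index,tree as in [assign_lca()].
#' @return data frame, one row per distinct collapsed peptide: `peptide`,
#'   `lca`, `rank`, `informative`, `food_class`, `n_matched_taxa`.
#' @export
assign_lca_table <- function(psms, index, tree) {
  keys <- unique(collapse_il(psms$peptide))
  rows <- lapply(keys, function(k) {
    a <- assign_lca(k, index, tree)
    data.frame(peptide = a$peptide, lca = a$lca, rank = a$rank,
               informative = a$informative, food_class = a$food_class,
               n_matched_taxa = length(a$matched_taxa),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(peptide = character(0), lca = character(0),
                      rank = character(0), informative = logical(0),
                      food_class = character(0),
                      n_matched_taxa = integer(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-sample dietary summary
#'
#' Cross-tabulates the taxonomically informative dietary peptides and PSMs
#' of each sample by assigned LCA and food class, with proportions over the
#' informative dietary PSMs (and peptides) of that sample. Peptides that
#' are uninformative, unassigned, or of conflicted/non-dietary food class
#' contribute nothing. Samples without a single informative dietary PSM are
#' flagged `"no dietary evidence"`.
#'
#' @param psms filtered PSM data frame (may span several samples).
#' @param index,tree as in [assign_lca()].
#' @return A `dietary_summary` list: `by_taxon` (data frame: `sample_id`,
#'   `lca`, `rank`, `food_class`, `n_peptides`, `n_psms`, `prop_psms`,
#'   `prop_peptides`) and `totals` (data frame per sample: informative
#'   peptide/PSM totals, milk peptide total, `flag`).
#' @export
summarize_dietary <- function(psms, index, tree) {
  samples <- unique(psms$sample_id)
  ass <- assign_lca_table(psms, index, tree)
  key <- collapse_il(psms$peptide)
  idx <- match(key, ass$peptide)
  psm_tab <- data.frame(sample_id = psms$sample_id,
                        peptide = key,
                        lca = ass$lca[idx], rank = ass$rank[idx],
                        informative = ass$informative[idx],
                        food_class = ass$food_class[idx],
                        stringsAsFactors = FALSE)
  keep <- psm_tab$informative & psm_tab$food_class != "other"
  by_rows <- list(); tot_rows <- list()
  for (s in samples) {
    d <- psm_tab[keep & psm_tab$sample_id == s, , drop = FALSE]
    n_psm <- nrow(d)
    n_pep <- length(unique(d$peptide))
    if (n_psm > 0L) {
      cell <- unique(d[, c("lca", "rank", "food_class")])
      for (i in seq_len(nrow(cell))) {
        dd <- d[d$lca == cell$lca[i] & d$food_class == cell$food_class[i], ,
                drop = FALSE]
        by_rows[[length(by_rows) + 1L]] <- data.frame(
          sample_id = s, lca = cell$lca[i], rank = cell$rank[i],
          food_class = cell$food_class[i],
          n_peptides = length(unique(dd$peptide)), n_psms = nrow(dd),
          prop_psms = nrow(dd) / n_psm,
          prop_peptides = length(unique(dd$peptide)) / n_pep,
          stringsAsFactors = FALSE)
      }
    }
    milk <- d[d$food_class %in% c("milk_whey", "milk_casein"), ,
              drop = FALSE]
    tot_rows[[length(tot_rows) + 1L]] <- data.frame(
      sample_id = s, n_informative_peptides = n_pep,
      n_informative_psms = n_psm,
      n_milk_peptides = length(unique(milk$peptide)),
      n_blood_peptides = length(unique(
        d$peptide[d$food_class == "blood_tissue"])),
      flag = if (n_psm == 0L) "no dietary evidence" else NA_character_,
      stringsAsFactors = FALSE)
  }
  by_taxon <- if (length(by_rows))
    do.call(rbind, c(by_rows, list(make.row.names = FALSE)))
  else
    data.frame(sample_id = character(0), lca = character(0),
               rank = character(0), food_class = character(0),
               n_peptides = integer(0), n_psms = integer(0),
               prop_psms = numeric(0), prop_peptides = numeric(0))
  ord <- order(by_taxon$sample_id, by_taxon$food_class, by_taxon$lca)
  totals <- if (length(tot_rows))
    do.call(rbind, c(tot_rows, list(make.row.names = FALSE)))
  else
    data.frame(sample_id = character(0), n_informative_peptides = integer(0),
               n_informative_psms = integer(0), n_milk_peptides = integer(0),
               n_blood_peptides = integer(0), flag = character(0))
  structure(list(by_taxon = by_taxon[ord, , drop = FALSE], totals = totals),
            class = "dietary_summary")
}

#' @export
print.dietary_summary <- function(x, ...) {
  cat("dietary_summary:", nrow(x$totals), "sample(s)\n")
  print(x$totals)
  invisible(x)
}

#' Write the per-peptide assignment table as TSV
#' @param summary_psms filtered PSM data frame.
#' @param index,tree as in [assign_lca()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(summary_psms, index, tree, path) {
  ass <- assign_lca_table(summary_psms, index, tree)
  key <- collapse_il(summary_psms$peptide)
  n <- table(paste(summary_psms$sample_id, key))
  rows <- unique(data.frame(sample_id = summary_psms$sample_id,
                            peptide = key, stringsAsFactors = FALSE))
  rows <- cbind(rows, ass[match(rows$peptide, ass$peptide),
                          c("lca", "rank", "informative", "food_class")])
  rows$n_psms <- as.integer(n[paste(rows$sample_id, rows$peptide)])
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
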