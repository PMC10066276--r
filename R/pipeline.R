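#' Run the full calculus analysis chain on one or more samples
#'
#' For each sample: PSM filtration (e-value, then protein support), OSSD
#' preservation assessment, and — only for samples that pass — peptide LCA
#' assignment, tryptic authentication, and the dietary summary. Samples
#' failing preservation keep their preservation block with the dietary
#' section marked not-assessed; this gating mirrors standard practice of
#' interpreting diet only in samples with an authentic oral signature.
#'
#' @param psms a PSM data frame, a path to one PSM TSV, or a directory of
#'   `*.psms.tsv` files (one per sample).
#' @param panel reference `protein_panel`
#'   (default [synthetic_metaproteome_panel()]).
#' @param ossd OSSD category map (default [default_ossd_map()]).
#' @param tree taxonomy (default [default_taxonomy()]).
#' @param params a [filter_params()].
#' @param threshold,min_proteins preservation pass rule (defaults 45, 10).
#' @param index optional prebuilt peptide index over `panel`.
#' @return A `pipeline_report` list: `config` (effective thresholds),
#'   `samples` (per-sample list with `filtration` counts, `preservation`,
#'   and, when assessed, `authentication`, `assignments`, `dietary`), and
#'   `summary` (the pooled [summarize_dietary()] of passing samples, `NULL`
#'   when none passed).
#' @export
run_pipeline <- function(psms, panel = NULL, ossd = NULL, tree = NULL,
                         params = filter_params(), threshold = 45,
                         min_proteins = 10L, index = NULL) {
  if (is.null(tree)) tree <- default_taxonomy()
  if (is.null(panel)) panel <- synthetic_metaproteome_panel(tree)
  if (is.null(ossd)) ossd <- default_ossd_map()
  if (is.null(index)) index <- build_peptide_index(panel, tree)
  if (is.character(psms)) {
    if (dir.exists(psms)) {
      files <- sort(list.files(psms, pattern = "\\.psms\\.tsv$",
                               full.names = TRUE))
      if (length(files) == 0L) {
        warning("no *.psms.tsv files in ", psms)
        psms <- data.frame(sample_id = character(0),
                           spectrum_id = character(0),
                           protein_accession = character(0),
                           peptide = character(0), prev_aa = character(0),
                           next_aa = character(0), e_value = numeric(0),
                           ion_score = numeric(0), mods = character(0))
      } else {
        psms <- do.call(rbind, lapply(files, read_psm_table))
      }
    } else if (file.exists(psms)) {
      psms <- read_psm_table(psms)
    } else stop("unreadable PSM input: ", psms)
  }
  config <- list(max_e_value = params$max_e_value,
                 min_unique_psms_per_protein =
                   params$min_unique_psms_per_protein,
                 uniqueness = params$uniqueness,
                 preservation_threshold = threshold,
                 preservation_min_proteins = min_proteins,
                 cn_ratio_range = c(2.9, 3.6),
                 index_params = index$params)
  out <- list(config = config, samples = list(), summary = NULL)
  passing <- list()
  for (s in unique(psms$sample_id)) {
    raw <- psms[psms$sample_id == s, , drop = FALSE]
    flt <- filter_psms(raw, params)
    filtration <- list(n_input = nrow(raw), n_retained = nrow(flt),
                       n_removed_e_value =
                         sum(raw$e_value > params$max_e_value),
                       n_removed_support =
                         sum(raw$e_value <= params$max_e_value) - nrow(flt))
    pres <- assess_preservation(flt$protein_accession, ossd,
                                threshold = threshold,
                                min_proteins = min_proteins,
                                sample_id = s)
    block <- list(sample_id = s, filtration = filtration,
                  preservation = pres)
    if (pres$passed) {
      block$authentication <- tryptic_fraction(flt, panel)
      block$dietary <- summarize_dietary(flt, index, tree)
      passing[[s]] <- flt
    } else {
      block$dietary <- "not assessed"
    }
    out$samples[[s]] <- block
  }
  if (length(passing))
    out$summary <- summarize_dietary(do.call(rbind, passing), index, tree)
  class(out) <- "pipeline_report"
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", length(x$samples), "sample(s),",
      sum(vapply(x$samples, function(s) s$preservation$passed, logical(1))),
      "passed preservation\n")
  if (!is.null(x$summary)) print(x$summary$totals)
  invisible(x)
}

#' Stacked proportion table of dietary evidence per sample
#'
#' Reshapes a [summarize_dietary()] result into a sample-by-(taxon x food
#' class) matrix of PSM proportions; each row of a sample with informative
#' PSMs sums to 1. Samples with none get an all-zero row.
#'
#' @param summary a `dietary_summary`.
#' @param value `"prop_psms"` (default), `"prop_peptides"`,
#'   `"n_psms"`, or `"n_peptides"`.
#' @return numeric matrix, rownames sample ids, colnames `lca|food_class`.
#' @export
render_proportions <- function(summary, value = "prop_psms") {
  stopifnot(inherits(summary, "dietary_summary"),
            value %in% c("prop_psms", "prop_peptides", "n_psms",
                         "n_peptides"))
  b <- summary$by_taxon
  samples <- summary$totals$sample_id
  cols <- unique(paste(b$lca, b$food_class, sep = "|"))
  m <- matrix(0, nrow = length(samples), ncol = length(cols),
              dimnames = list(samples, cols))
  if (nrow(b))
    m[cbind(match(b$sample_id, samples),
            match(paste(b$lca, b$food_class, sep = "|"), cols))] <-
      b[[value]]
  m
}

#' Write a pipeline report to JSON
#'
#' Serializes the per-sample blocks (filtration counts, preservation
#' scores, authentication, dietary tables) plus the effective
#' configuration, so every run documents its thresholds.
#'
#' @param report a `pipeline_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  ser <- list(config = report$config,
              samples = lapply(report$samples, function(s) {
                p <- s$preservation
                list(sample_id = s$sample_id, filtration = s$filtration,
                     preservation = list(counts = as.list(p$counts),
                                         total_ossd = p$total_ossd,
                                         score = p$score,
                                         passed = p$passed, flag = p$flag),
                     authentication = if (!is.null(s$authentication))
                       list(fraction = s$authentication$fraction,
                            non_tryptic_by_class =
                              as.list(s$authentication$non_tryptic_by_class)),
                     dietary = if (inherits(s$dietary, "dietary_summary"))
                       list(by_taxon = s$dietary$by_taxon,
                            totals = s$dietary$totals)
                     else s$dietary)
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
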