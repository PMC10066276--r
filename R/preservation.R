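OSSD_CATEGORIES <- c("oral_microbiome", "immune", "lab_contaminant",
                     "env_contaminant")

#' Read an OSSD category map
#'
#' The Oral Signature Screening Database map assigns reference accessions
#' to one of four categories: `oral_microbiome`, `immune`,
#' `lab_contaminant`, `env_contaminant`. Accessions absent from the map
#' (e.g. dietary proteins) have no OSSD category and are ignored by the
#' preservation score.
#'
#' @param path TSV with columns `accession`, `category`.
#' @return named character vector, accession -> category.
#' @export
read_ossd_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("accession", "category"), names(df))
  if (length(miss))
    stop("OSSD map missing column(s): ", paste(miss, collapse = ", "))
  bad <- !df$category %in% OSSD_CATEGORIES
  if (any(bad))
    stop("unknown OSSD category: ",
         paste(unique(df$category[bad]), collapse = ", "))
  stats::setNames(df$category, df$accession)
}

#' Bundled illustrative OSSD map
#'
#' A small default map covering the accessions of the synthetic
#' metaproteome panel (see [synthetic_metaproteome_panel()]). The full
#' curated screening database used on real data is a user-supplied input;
#' this default exists so the pipeline and simulator run self-contained.
#'
#' @return named character vector, accession -> category.
#' @export
default_ossd_map <- function() {
  read_ossd_map(system.file("extdata", "ossd_map_synthetic.tsv",
                            package = "paleocalc", mustWork = TRUE))
}

#' Oral-signature preservation assessment
#'
#' Scores how authentically "oral" a calculus metaproteome looks: the
#' number of oral-microbiome plus immune proteins, divided by the total
#' number of OSSD-listed proteins identified, times 100. A sample passes
#' when the score is strictly above `threshold` and at least `min_proteins`
#' OSSD proteins were identified. Counting is protein-level: an accession
#' contributes once however many PSMs support it.
#'
#' @param accessions character vector of protein accessions identified in
#'   one sample (after PSM filtration); duplicates are collapsed.
#' @param ossd named character vector from [read_ossd_map()].
#' @param threshold pass threshold on the 0-100 score (default 45, strict).
#' @param min_proteins minimum total OSSD proteins (default 10, inclusive).
#' @param sample_id optional label carried into the result.
#' @return A `preservation_result` list: `sample_id`, `counts` (named
#'   integer per category), `total_ossd`, `score` (`NA` when no OSSD
#'   protein was seen), `passed`, `flag`.
#' @examples
#' ossd <- setNames(rep(c("oral_microbiome", "env_contaminant"), c(3, 2)),
#'                  c("m1", "m2", "m3", "c1", "c2"))
#' assess_preservation(c("m1", "m2", "c1"), ossd)
#' @export
assess_preservation <- function(accessions, ossd, threshold = 45,
                                min_proteins = 10L, sample_id = NA_character_) {
  accessions <- unique(accessions)
  cat_of <- ossd[accessions]
  cat_of <- cat_of[!is.na(cat_of)]
  counts <- vapply(OSSD_CATEGORIES, function(cc) sum(cat_of == cc),
                   integer(1))
  total <- length(cat_of)
  if (total == 0L) {
    score <- NA_real_
    passed <- FALSE
    flag <- "no OSSD proteins identified; score undefined"
  } else {
    score <- 100 * (counts[["oral_microbiome"]] + counts[["immune"]]) / total
    passed <- (score > threshold) && (total >= min_proteins)
    flag <- if (passed) NA_character_ else if (total < min_proteins)
      "fewer OSSD proteins than required" else "score at or below threshold"
  }
  structure(list(sample_id = sample_id, counts = counts, total_ossd = total,
                 score = score, passed = passed, flag = flag),
            class = "preservation_result")
}

#' @export
print.preservation_result <- function(x, ...) {
  cat("preservation_result [", x$sample_id, "]: score =",
      if (is.na(x$score)) "NA" else round(x$score, 1),
      "over", x$total_ossd, "OSSD proteins;",
      if (x$passed) "PASSED" else "failed", "\n")
  invisible(x)
}

#' Carbon-to-nitrogen atomic ratio for collagen quality control
#'
#' Converts elemental mass percentages to the atomic C/N ratio
#' `(C% / 12.011) / (N% / 14.007)`. Collagen with a ratio inside the
#' accepted window (2.9 to 3.6, endpoints included) is considered suitable
#' for reliable radiocarbon measurement.
#'
#' @param carbon_mass_percent,nitrogen_mass_percent elemental mass
#'   percentages in `(0, 100]`.
#' @param range accepted inclusive window (default `c(2.9, 3.6)`).
#' @return list with `ratio` and logical `accepted`.
#' @export
atomic_cn_ratio <- function(carbon_mass_percent, nitrogen_mass_percent,
                            range = c(2.9, 3.6)) {
  if (nitrogen_mass_percent <= 0) stop("nitrogen mass percent must be > 0")
  stopifnot(carbon_mass_percent > 0, carbon_mass_percent <= 100,
            nitrogen_mass_percent <= 100)
  ratio <- (carbon_mass_percent / 12.011) / (nitrogen_mass_percent / 14.007)
  list(ratio = ratio, accepted = ratio >= range[1L] && ratio <= range[2L])
}
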