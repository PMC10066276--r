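#' Construct a taxonomy tree
#'
#' A taxonomy tree is a rooted tree over taxon-name strings, stored as a
#' parent map. The root maps to itself. Least-common-ancestor queries over
#' this tree are the basis of all taxonomic specificity claims made by the
#' peptide assignment stage.
#'
#' @param child character vector of child node names.
#' @param parent character vector of parent node names, parallel to `child`.
#'   The root is the (single) name that appears as a parent but never as a
#'   child; it is added automatically with itself as parent.
#' @param rank optional character vector of rank labels parallel to `child`
#'   (e.g. "genus", "species"); the root gets rank "root".
#' @return An object of class `taxonomy_tree`: a list with elements
#'   `nodes` (character), `parent` (named character), `rank` (named
#'   character) and `root` (string).
#' @examples
#' tr <- taxonomy_tree(c("Bos", "Bos taurus"), c("Mammalia", "Bos"),
#'                     c("genus", "species"))
#' taxon_lca(tr, c("Bos taurus", "Bos"))
#' @export
taxonomy_tree <- function(child, parent, rank = NULL) {
  stopifnot(is.character(child), is.character(parent),
            length(child) == length(parent))
  if (anyDuplicated(child))
    stop("duplicated child node(s): ",
         paste(unique(child[duplicated(child)]), collapse = ", "))
  roots <- setdiff(parent, child)
  if (length(roots) != 1L)
    stop("tree must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  pm <- c(stats::setNames(parent, child), stats::setNames(roots, roots))
  nodes <- names(pm)
  rk <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  if (!is.null(rank)) rk[child] <- rank
  rk[roots] <- "root"
  # cycle check: every node must reach the root
  for (n in nodes) {
    seen <- character(0)
    cur <- n
    while (cur != roots) {
      if (cur %in% seen) stop("cycle detected at node: ", cur)
      seen <- c(seen, cur)
      cur <- pm[[cur]]
    }
  }
  structure(list(nodes = nodes, parent = pm, rank = rk, root = roots),
            class = "taxonomy_tree")
}

#' Read a taxonomy tree from an edge-list TSV
#'
#' Expects columns `child`, `parent`, `rank` (rank optional).
#'
#' @param path path to a tab-separated edge list.
#' @return A [taxonomy_tree()].
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("child", "parent")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("taxonomy file missing column(s): ", paste(miss, collapse = ", "))
  taxonomy_tree(df$child, df$parent,
                rank = if ("rank" %in% names(df)) df$rank else NULL)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", length(x$nodes), "nodes, root =", x$root, "\n")
  invisible(x)
}

#' Ancestors of a node (from the node itself up to the root)
#' @param tree a [taxonomy_tree()].
#' @param node a node name.
#' @return character vector, first element `node`, last the root.
#' @export
taxon_ancestors <- function(tree, node) {
  if (!node %in% tree$nodes) stop("unknown taxon: ", node)
  out <- node
  while (node != tree$root) {
    node <- tree$parent[[node]]
    out <- c(out, node)
  }
  out
}

#' Least common ancestor of a set of taxa
#'
#' Walks parent links; the LCA of a single taxon is itself, of an empty set
#' is `NA`.
#'
#' @param tree a [taxonomy_tree()].
#' @param taxa character vector of node names.
#' @return node name, or `NA_character_` for an empty set.
#' @export
taxon_lca <- function(tree, taxa) {
  taxa <- unique(taxa)
  if (length(taxa) == 0L) return(NA_character_)
  paths <- lapply(taxa, function(t) rev(taxon_ancestors(tree, t)))
  k <- min(lengths(paths))
  lca <- tree$root
  for (i in seq_len(k)) {
    step <- vapply(paths, `[[`, character(1), i)
    if (all(step == step[[1L]])) lca <- step[[1L]] else break
  }
  lca
}

#' Is `node` equal to or a descendant of `ancestor`?
#' @inheritParams taxon_ancestors
#' @param ancestor candidate ancestor node name.
#' @return logical.
#' @export
taxon_is_descendant <- function(tree, node, ancestor) {
  ancestor %in% taxon_ancestors(tree, node)
}

#' Bundled default taxonomy
#'
#' The mammalian dairy/livestock lineage used throughout: the pecoran
#' ruminants (Bovidae with Bovinae and Caprinae, plus Cervidae so that
#' infraorder-level calls are reachable), the equids joined to the ruminants
#' only at the mammalian root, plus host, swine, and common oral bacterial
#' taxa used by the synthetic metaproteome.
#'
#' @return A [taxonomy_tree()].
#' @export
default_taxonomy <- function() {
  edges <- matrix(c(
    "Mammalia",            "root",        "class",
    "Bacteria",            "root",        "superkingdom",
    "Pecora",              "Mammalia",    "infraorder",
    "Equidae",             "Mammalia",    "family",
    "Hominidae",           "Mammalia",    "family",
    "Suidae",              "Mammalia",    "family",
    "Bovidae",             "Pecora",      "family",
    "Cervidae",            "Pecora",      "family",
    "Bovinae",             "Bovidae",     "subfamily",
    "Caprinae",            "Bovidae",     "subfamily",
    "Bos",                 "Bovinae",     "genus",
    "Bison bison",         "Bovinae",     "species",
    "Bos taurus",          "Bos",         "species",
    "Bos indicus",         "Bos",         "species",
    "Bos grunniens/mutus", "Bos",         "species",
    "Ovis",                "Caprinae",    "genus",
    "Capra",               "Caprinae",    "genus",
    "Ovis aries",          "Ovis",        "species",
    "Capra hircus",        "Capra",       "species",
    "Cervus elaphus",      "Cervidae",    "species",
    "Equus",               "Equidae",     "genus",
    "Equus caballus",      "Equus",       "species",
    "Equus asinus",        "Equus",       "species",
    "Homo sapiens",        "Hominidae",   "species",
    "Sus scrofa",          "Suidae",      "species",
    "Streptococcus mitis",        "Bacteria", "species",
    "Streptococcus sanguinis",    "Bacteria", "species",
    "Actinomyces oris",           "Bacteria", "species",
    "Tannerella forsythia",       "Bacteria", "species",
    "Porphyromonas gingivalis",   "Bacteria", "species",
    "Fusobacterium nucleatum",    "Bacteria", "species",
    "Rothia dentocariosa",        "Bacteria", "species",
    "Veillonella parvula",        "Bacteria", "species",
    "Neisseria flavescens",       "Bacteria", "species",
    "Treponema denticola",        "Bacteria", "species"
  ), ncol = 3L, byrow = TRUE)
  taxonomy_tree(edges[, 1L], edges[, 2L], edges[, 3L])
}
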