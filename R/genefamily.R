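# Gene family and gene-tree distribution containers.

#' Define a gene family
#'
#' A gene family is a set of homologous sequences (orthologs, paralogs,
#' possibly several individuals per species) analyzed as one tree.  Each leaf
#' is mapped to exactly one species; several leaves may map to the same
#' species, and the family's species set may be a strict subset of the full
#' species list.
#'
#' @param id integer family identifier.
#' @param leaves character vector of leaf labels.
#' @param species character vector of all species names; leaves are mapped by
#'   longest-substring matching (see [map_leaves_to_species()]), unless an
#'   explicit `leaf_map` is given.
#' @param leaf_map optional named character vector leaf -> species.
#' @param ignore_case passed to [map_leaves_to_species()].
#' @return object of class `gene_family` with elements `id`, `leaves`,
#'   `leaf_species` (named map) and `species` (sorted species present).
#' @export
gene_family <- function(id, leaves, species, leaf_map = NULL, ignore_case = FALSE) {
  if (is.null(leaf_map)) leaf_map <- map_leaves_to_species(leaves, species, ignore_case)
  if (!all(leaves %in% names(leaf_map))) stop("leaf_map must cover every leaf")
  leaf_map <- leaf_map[leaves]
  structure(list(id = as.integer(id), leaves = leaves,
                 leaf_species = leaf_map,
                 species = sort(unique(unname(leaf_map)))),
            class = "gene_family")
}

#' Weighted distribution of unrooted gene-tree topologies
#'
#' Wraps a gene family together with a set of distinct unrooted topologies
#' and their resampling weights (posterior frequencies from an upstream
#' Bayesian gene-tree analysis, or frequencies from the uncertainty
#' generator).
#'
#' @param family a [gene_family()].
#' @param trees list of `phylo` objects on the family's exact leaf multiset.
#' @param weights non-negative weights; normalized to sum to one.
#' @param assume_distinct skip the canonical-key deduplication (used by
#'   generators whose output is distinct by construction; saves quadratic
#'   work on very large families).
#' @return object of class `gene_tree_distribution` with elements `family`,
#'   `trees`, `weights`.
#' @export
gene_tree_distribution <- function(family, trees, weights = NULL,
                                   assume_distinct = FALSE) {
  stopifnot(inherits(family, "gene_family"))
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no topologies")
  if (is.null(weights)) weights <- rep(1, length(trees))
  if (length(weights) != length(trees)) stop("one weight per topology required")
  if (any(weights < 0)) stop("weights must be non-negative")
  for (t in trees) {
    if (!identical(sort(t$tip.label), sort(family$leaves)))
      stop("topology leaf multiset differs from the family's leaves")
  }
  if (!assume_distinct) {
    keys <- vapply(trees, topology_key, "")
    if (anyDuplicated(keys)) {
      first <- !duplicated(keys)
      weights <- as.numeric(tapply(weights, factor(keys, levels = keys[first]), sum))
      trees <- trees[first]
    }
  }
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero")
  if (abs(s - 1) > 1e-9) weights <- weights / s
  structure(list(family = family, trees = trees, weights = weights),
            class = "gene_tree_distribution")
}

#' @export
print.gene_tree_distribution <- function(x, ...) {
  cat("gene_tree_distribution: family", x$family$id, "-",
      length(x$family$leaves), "leaves,", length(x$trees), "topologies,",
      length(x$family$species), "species\n")
  invisible(x)
}

#' @export
print.gene_family <- function(x, ...) {
  cat("gene_family", x$id, ":", length(x$leaves), "leaves over",
      length(x$species), "species\n")
  invisible(x)
}
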