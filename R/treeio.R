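# Reading and writing gene-tree collections, leaf-to-species mapping and the
# split-based accuracy/consensus machinery.

#' Read a weighted collection of gene-tree topologies
#'
#' Reads one gene family's tree sample from a Newick list file (one tree per
#' line, with an optional leading weight column separated by whitespace) or
#' from a Nexus TREES block.  Duplicate topologies are collapsed and their
#' weights (or counts) accumulated, then normalized to sum to one; the raw
#' counts are kept for reporting.
#'
#' @param path file path.
#' @param format `"auto"` (default; Nexus is detected from the `#NEXUS`
#'   header), `"newick"` or `"nexus"`.
#' @return an object of class `gene_tree_sample`: a list with elements
#'   `trees` (list of `phylo`, topologies only), `weights` (normalized),
#'   `counts` (raw weights as read).
#' @export
read_gene_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (length(lines) && grepl("^#NEXUS", toupper(trimws(lines[1])))) "nexus" else "newick"
  if (format == "nexus") {
    trees <- ape::read.nexus(path)
    if (inherits(trees, "phylo")) trees <- list(trees)
    w <- rep(1, length(trees))
  } else {
    keep <- which(nzchar(trimws(lines)))
    if (!length(keep)) stop("empty tree file: ", path)
    trees <- list(); w <- numeric(0)
    for (i in keep) {
      ln <- trimws(lines[i])
      m <- regmatches(ln, regexec("^([0-9.eE+-]+)[ \t]+(\\(.*)$", ln))[[1]]
      if (length(m) == 3) { wt <- as.numeric(m[2]); txt <- m[3] }
      else { wt <- 1; txt <- ln }
      phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
      if (is.null(phy) || is.na(wt))
        stop("malformed Newick at line ", i, " of ", path)
      trees[[length(trees) + 1L]] <- phy
      w <- c(w, wt)
    }
  }
  # duplicate collapse respects the file's own semantics: rooted trees are
  # distinct unless their rooted topologies agree (unrooted trees compare
  # unrooted); the model-level distribution constructor collapses further
  keys <- vapply(trees, function(t)
    if (ape::Ntip(t) >= 3L && ape::is.rooted(t)) rooted_key(t) else topology_key(t), "")
  first <- !duplicated(keys)
  counts <- as.numeric(tapply(w, factor(keys, levels = keys[first]), sum))
  trees <- trees[first]
  structure(list(trees = trees, weights = counts / sum(counts), counts = counts),
            class = "gene_tree_sample")
}

#' Write a weighted gene-tree collection
#'
#' Emits the tab-separated `weight<TAB>newick` dialect read back by
#' [read_gene_trees()].
#'
#' @param x a `gene_tree_sample`, `gene_tree_distribution`, or list of `phylo`.
#' @param weights optional weights when `x` is a plain list.
#' @param path output file.
#' @export
write_gene_trees <- function(x, path, weights = NULL) {
  if (inherits(x, c("gene_tree_sample", "gene_tree_distribution"))) {
    trees <- x$trees; weights <- x$weights
  } else trees <- x
  if (is.null(weights)) weights <- rep(1 / length(trees), length(trees))
  txt <- vapply(trees, function(t) ape::write.tree(t), "")
  writeLines(paste(format(weights, digits = 10, trim = TRUE), txt, sep = "\t"), path)
  invisible(path)
}

#' Read a species list (one name per line)
#' @param path file path.
#' @export
read_species_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  if (!length(x)) stop("empty species list: ", path)
  if (anyDuplicated(x)) stop("duplicated species names in ", path)
  x
}

#' Map gene-tree leaves to species by name containment
#'
#' Each leaf label is matched to the species whose name occurs in it as a
#' substring; when several species names match, the longest one wins.  This is
#' the minimal-input convention under which users only supply a species list
#' and leaf labels are expected to embed species names.
#'
#' @param leaves character vector of leaf labels.
#' @param species character vector of species names (unique, non-empty).
#' @param ignore_case match case-insensitively.
#' @return named character vector: `leaves -> species`.
#' @export
map_leaves_to_species <- function(leaves, species, ignore_case = FALSE) {
  if (!length(species) || anyDuplicated(species) || any(!nzchar(species)))
    stop("species names must be non-empty and unique")
  lv <- if (ignore_case) tolower(leaves) else leaves
  sp <- if (ignore_case) tolower(species) else species
  out <- character(length(leaves))
  for (i in seq_along(leaves)) {
    hit <- which(vapply(sp, function(s) grepl(s, lv[i], fixed = TRUE), TRUE))
    if (!length(hit)) stop("leaf '", leaves[i], "' matches no species name")
    len <- nchar(sp[hit])
    best <- hit[len == max(len)]
    if (length(best) > 1L)
      stop("leaf '", leaves[i], "' matches several species names of equal length: ",
           paste(species[best], collapse = ", "))
    out[i] <- species[best]
  }
  names(out) <- leaves
  out
}

#' Bipartitions of a tree
#'
#' Returns the (by default nontrivial) bipartitions of the unrooted topology.
#' In multree mode the two sides are species-label multisets obtained through
#' `leaf_map`, which is how the mulRF comparison reads a multi-labeled gene
#' tree.
#'
#' @param tree a `phylo`.
#' @param nontrivial_only drop splits with a single leaf on one side.
#' @param multree treat sides as species multisets via `leaf_map`.
#' @param leaf_map named character vector (leaf -> species), required when
#'   `multree = TRUE`.
#' @return list of splits; each split is a list of two character vectors
#'   (canonical orientation: lexicographically smaller side first).
#' @export
bipartitions <- function(tree, nontrivial_only = TRUE, multree = FALSE, leaf_map = NULL) {
  if (ape::Ntip(tree) < 3L) stop("tree must have at least 3 leaves")
  phy <- ape::unroot(tree)
  n <- ape::Ntip(phy)
  below <- node_clades(phy)
  labs <- phy$tip.label
  res <- list()
  seen <- character(0)
  for (v in seq_len(n + phy$Nnode)) {
    if (v == n + 1L) next
    side <- below[[v]]
    if (length(side) < 1L || length(side) >= n) next
    if (nontrivial_only && (length(side) < 2L || n - length(side) < 2L)) next
    other <- setdiff2_multi(labs, side)
    a <- sort(side); b <- sort(other)
    if (multree) {
      if (is.null(leaf_map)) stop("multree mode needs a leaf_map")
      a <- sort(unname(leaf_map[a])); b <- sort(unname(leaf_map[b]))
    }
    ka <- paste(a, collapse = "\r"); kb <- paste(b, collapse = "\r")
    sp <- if (ka <= kb) list(a, b) else list(b, a)
    key <- if (ka <= kb) paste(ka, kb, sep = "|") else paste(kb, ka, sep = "|")
    if (!multree && key %in% seen) next   # root-child duplicate
    seen <- c(seen, key)
    res[[length(res) + 1L]] <- sp
  }
  res
}

#' Split accuracy of a species-tree estimate
#'
#' Fraction of the nontrivial splits of the true unrooted species tree that
#' are present in the estimate.  Equals 1 exactly when the unrooted topologies
#' agree (for a fully resolved estimate) and 0 for a star estimate.
#'
#' @param true_tree fully resolved `phylo` (the truth).
#' @param estimate `phylo` on the same leaf set (may be multifurcating).
#' @return numeric in `[0, 1]`.
#' @export
split_accuracy <- function(true_tree, estimate) {
  if (!setequal(true_tree$tip.label, estimate$tip.label) ||
      length(true_tree$tip.label) != length(estimate$tip.label))
    stop("trees must share the same leaf set")
  ts <- tree_split_keys(true_tree)
  if (!length(ts)) stop("true tree has no nontrivial splits")
  es <- tree_split_keys(estimate)
  sum(ts %in% es) / length(ts)
}

#' Weighted majority-rule consensus
#'
#' Builds the tree containing exactly the splits (unrooted mode) or clades
#' (rooted mode) whose cumulative weight exceeds `p`.  With `p >= 0.5` the
#' retained splits are pairwise compatible by construction.
#'
#' @param trees list of `phylo` on a common leaf set.
#' @param weights optional non-negative weights (default: equal).
#' @param p threshold, at least 0.5.
#' @param rooted build a rooted consensus from clades instead of splits.
#' @return a `phylo`, possibly multifurcating.
#' @export
majority_consensus <- function(trees, weights = NULL, p = 0.5, rooted = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree sample")
  if (p < 0.5) stop("threshold must be at least 0.5")
  if (is.null(weights)) weights <- rep(1, length(trees))
  weights <- weights / sum(weights)
  labs <- sort(trees[[1L]]$tip.label)
  n <- length(labs)
  tally <- new.env(parent = emptyenv())
  keep_cluster <- new.env(parent = emptyenv())
  for (i in seq_along(trees)) {
    phy <- trees[[i]]
    if (!identical(sort(phy$tip.label), labs)) stop("trees must share one leaf set")
    if (rooted) {
      below <- node_clades(phy)
      cls <- lapply((n + 1L):(n + phy$Nnode), function(v) sort(below[[v]]))
      cls <- cls[vapply(cls, function(x) length(x) < n && length(x) > 1L, TRUE)]
    } else {
      phyu <- ape::unroot(phy)
      below <- node_clades(phyu)
      ref <- labs[1L]
      cls <- list()
      for (v in seq_len(n + phyu$Nnode)) {
        if (v == n + 1L) next
        side <- below[[v]]
        if (length(side) < 2L || length(side) > n - 2L) next
        if (ref %in% side) side <- setdiff(phyu$tip.label, side)
        cls[[length(cls) + 1L]] <- sort(side)
      }
      cls <- unique(cls)
    }
    for (cl in cls) {
      key <- paste(cl, collapse = "\r")
      tally[[key]] <- (if (is.null(tally[[key]])) 0 else tally[[key]]) + weights[i]
      keep_cluster[[key]] <- cl
    }
  }
  keys <- ls(tally)
  keep <- keys[vapply(keys, function(k) tally[[k]] > p + 1e-12, TRUE)]
  clusters <- lapply(keep, function(k) keep_cluster[[k]])
  out <- clusters_to_phylo(clusters, labs)
  if (!rooted) out <- ape::unroot(out)
  attr(out, "split_support") <- data.frame(
    split = keys, support = vapply(keys, function(k) tally[[k]], 0),
    row.names = NULL)
  out
}
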