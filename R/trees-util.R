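# Internal tree plumbing: conversions between ape's phylo objects and the
# integer representations used by the C++ kernels, canonical topology keys,
# split extraction, weighted consensus and topology enumeration.

#' @importFrom ape read.tree write.tree unroot is.rooted is.binary keep.tip
#'   drop.tip Ntip Nnode rtree rcoal rphylo root
NULL

# rooted binary phylo -> 0-based parent vector; leaves numbered by `species`
phylo_to_parent <- function(phy, species) {
  n <- length(phy$tip.label)
  stopifnot(n == length(species))
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    stop("species tree must be rooted and binary")
  idx <- match(phy$tip.label, species)
  if (anyNA(idx)) stop("species tree labels do not match the species list")
  remap <- function(v) ifelse(v <= n, idx[v] - 1L, v - 1L)
  par <- rep(-1L, 2L * n - 1L)
  for (r in seq_len(nrow(phy$edge)))
    par[remap(phy$edge[r, 2L]) + 1L] <- remap(phy$edge[r, 1L])
  par
}

# inverse of phylo_to_parent (via newick, which also normalizes the structure)
parent_to_phylo <- function(par, species) {
  n <- (length(par) + 1L) %/% 2L
  kids <- vector("list", length(par))
  root <- -1L
  for (v in seq_along(par)) {
    p <- par[v]
    if (p < 0L) root <- v - 1L else kids[[p + 1L]] <- c(kids[[p + 1L]], v - 1L)
  }
  nwk <- function(v) {
    if (v < n) species[v + 1L]
    else {
      ch <- kids[[v + 1L]]
      paste0("(", paste(vapply(ch, nwk, ""), collapse = ","), ")")
    }
  }
  ape::read.tree(text = paste0(nwk(root), ";"))
}

# unrooted (or rooted; gets unrooted) phylo -> edge matrix + leaf slot mapping.
# `leaves` fixes the leaf slot order; duplicated labels are assigned to the
# remaining slots with the same label in order of appearance.
phylo_to_utree <- function(phy, leaves = NULL) {
  m <- length(phy$tip.label)
  if (m >= 3L) phy <- ape::unroot(phy)
  if (is.null(leaves)) leaves <- phy$tip.label
  stopifnot(length(leaves) == m)
  if (m <= 2L) {
    slot <- match(phy$tip.label, leaves)
    edges <- if (m == 2L) matrix(c(slot[1L] - 1L, slot[2L] - 1L), 1L, 2L)
             else matrix(integer(0), 0L, 2L)
    storage.mode(edges) <- "integer"
    lens <- if (!is.null(phy$edge.length)) sum(phy$edge.length) else NULL
    return(list(edges = edges, leaves = leaves, lengths = lens))
  }
  avail <- split(seq_len(m), leaves)
  used <- new.env(parent = emptyenv())
  slot <- integer(m)
  for (i in seq_len(m)) {
    lab <- phy$tip.label[i]
    k <- if (is.null(used[[lab]])) 1L else used[[lab]] + 1L
    slots <- avail[[lab]]
    if (is.null(slots) || k > length(slots))
      stop("leaf label ", lab, " not in the expected leaf multiset")
    slot[i] <- slots[k]
    used[[lab]] <- k
  }
  remap <- function(v) ifelse(v <= m, slot[v] - 1L, v - 1L)
  edges <- cbind(remap(phy$edge[, 1L]), remap(phy$edge[, 2L]))
  storage.mode(edges) <- "integer"
  list(edges = edges, leaves = leaves,
       lengths = if (!is.null(phy$edge.length)) phy$edge.length else NULL)
}

# edge matrix (0-based, leaves 0..m-1) -> phylo
utree_to_phylo <- function(edges, labels) {
  m <- length(labels)
  if (m == 1L) return(ape::read.tree(text = paste0(labels, ";")))
  if (m == 2L) return(ape::read.tree(text = paste0("(", labels[1L], ",", labels[2L], ");")))
  nn <- 2L * m - 2L
  adj <- vector("list", nn)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L] + 1L; b <- edges[r, 2L] + 1L
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  anchor <- adj[[1L]][1L]  # internal node next to leaf slot 1
  nwk <- function(v, from) {
    if (v <= m) return(labels[v])
    ch <- setdiff(adj[[v]], from)
    paste0("(", paste(vapply(ch, function(w) nwk(w, v), ""), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(nwk(anchor, -1L), ";"))
}

# label sets below each internal node (on the tree as stored)
node_clades <- function(phy) {
  n <- ape::Ntip(phy)
  nn <- n + phy$Nnode
  below <- vector("list", nn)
  for (i in seq_len(n)) below[[i]] <- phy$tip.label[i]
  po <- ape::reorder.phylo(phy, "postorder")
  for (r in seq_len(nrow(po$edge))) {
    a <- po$edge[r, 1L]; b <- po$edge[r, 2L]
    below[[a]] <- c(below[[a]], below[[b]])
  }
  below
}

split_key_chr <- function(side, all_labels) {
  a <- sort(side)
  b <- sort(setdiff2_multi(all_labels, side))
  ka <- paste(a, collapse = "\r")
  kb <- paste(b, collapse = "\r")
  if (ka <= kb) ka else kb
}

# multiset difference (setdiff drops duplicates, which breaks multrees)
setdiff2_multi <- function(all, part) {
  out <- all
  for (x in part) {
    i <- match(x, out)
    if (!is.na(i)) out <- out[-i]
  }
  out
}

# canonical keys of the nontrivial splits of the unrooted topology
tree_split_keys <- function(phy, nontrivial_only = TRUE) {
  phy <- ape::unroot(phy)
  n <- ape::Ntip(phy)
  below <- node_clades(phy)
  labs <- phy$tip.label
  keys <- character(0)
  root <- n + 1L
  for (v in seq_len(n + phy$Nnode)) {
    if (v == root) next
    side <- below[[v]]
    if (nontrivial_only && (length(side) < 2L || n - length(side) < 2L)) next
    if (length(side) < 1L || length(side) >= n) next
    keys <- c(keys, split_key_chr(side, labs))
  }
  sort(unique(keys))
}

# canonical key for an unrooted topology (distinct leaf labels assumed)
topology_key <- function(phy) {
  n <- ape::Ntip(phy)
  if (n < 4L) return(paste(sort(phy$tip.label), collapse = ","))
  paste(tree_split_keys(phy), collapse = ";")
}

# canonical key for a rooted topology (clade multiset)
rooted_key <- function(phy) {
  below <- node_clades(phy)
  n <- ape::Ntip(phy)
  keys <- vapply((n + 1L):(n + phy$Nnode), function(v)
    paste(sort(below[[v]]), collapse = "\r"), "")
  paste(sort(keys), collapse = ";")
}

# build a (possibly multifurcating) rooted tree from a laminar cluster family
clusters_to_phylo <- function(clusters, labels) {
  build <- function(set, cl) {
    inside <- cl[vapply(cl, function(x) all(x %in% set) && length(x) < length(set), TRUE)]
    if (length(inside)) {
      maximal <- inside[vapply(seq_along(inside), function(i) {
        !any(vapply(seq_along(inside), function(j)
          j != i && length(inside[[j]]) > length(inside[[i]]) &&
            all(inside[[i]] %in% inside[[j]]), TRUE))
      }, TRUE)]
    } else maximal <- list()
    used <- unlist(maximal)
    singles <- setdiff(set, used)
    parts <- c(lapply(maximal, function(s) build(s, cl)), as.list(singles))
    if (length(parts) == 1L) parts[[1L]]
    else paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(labels, clusters), ";"))
}

# enumerate all unrooted binary topologies on n >= 3 leaves (edge matrices)
enum_utrees <- function(n) {
  stopifnot(n >= 3L)
  base <- list(list(edges = matrix(c(0L, n, 1L, n, 2L, n), ncol = 2, byrow = TRUE),
                    next_int = n + 1L))
  k <- 3L
  trees <- base
  while (k < n) {
    out <- list()
    for (tr in trees) {
      e <- tr$edges
      for (r in seq_len(nrow(e))) {
        c_new <- tr$next_int
        e2 <- rbind(e[-r, , drop = FALSE],
                    c(e[r, 1L], c_new), c(e[r, 2L], c_new), c(k, c_new))
        storage.mode(e2) <- "integer"
        out[[length(out) + 1L]] <- list(edges = e2, next_int = c_new + 1L)
      }
    }
    trees <- out
    k <- k + 1L
  }
  lapply(trees, `[[`, "edges")
}

#' Enumerate all tree topologies on a label set
#'
#' Generates every unrooted (or rooted) binary topology on the given leaf
#' labels by sequential leaf insertion.  There are \eqn{(2n-5)!!} unrooted and
#' \eqn{(2n-3)!!} rooted topologies, so this is only feasible for small
#' \eqn{n}; it backs the brute-force partition function and the exhaustive
#' search oracles.
#'
#' @param labels character vector of leaf labels (may contain duplicates for
#'   multi-labeled enumeration; leaves are still treated as distinct).
#' @param rooted logical; enumerate rooted topologies instead of unrooted.
#' @param max_leaves guard against accidental combinatorial explosions.
#' @return list of `phylo` objects.
#' @export
all_topologies <- function(labels, rooted = FALSE, max_leaves = 9L) {
  n <- length(labels)
  if (n > max_leaves) stop("refusing to enumerate topologies for more than ",
                           max_leaves, " leaves")
  if (rooted) {
    sent <- ".__root__"
    ut <- all_topologies(c(labels, sent), rooted = FALSE, max_leaves = max_leaves + 1L)
    return(lapply(ut, function(phy) {
      phy <- ape::root(phy, outgroup = sent, resolve.root = TRUE)
      ape::drop.tip(phy, sent)
    }))
  }
  if (n < 3L) stop("need at least 3 leaves")
  lapply(enum_utrees(n), utree_to_phylo, labels = labels)
}

# random rooted binary species tree with the given labels (uniform shapes
# are not required here; used for initialization and reference trees)
random_species_tree <- function(species) {
  phy <- ape::rtree(length(species), rooted = TRUE)
  phy$tip.label <- sample(species)
  phy$edge.length <- NULL
  phy
}
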