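# Independent oracle implementations and small generators used across the
# test suite.  Everything here is deliberately naive: enumeration and direct
# set manipulation, no shared code with the package's kernels beyond basic
# tree containers.

# random rooted binary species tree on the given labels (topology only)
rand_stree <- function(labels) {
  phy <- ape::rtree(length(labels), rooted = TRUE)
  phy$tip.label <- sample(labels)
  phy$edge.length <- NULL
  phy
}

# random gene tree: nl leaves drawn (with replacement) from `species`
rand_gene <- function(species, nl, prefix = "g") {
  spp <- sample(species, nl, replace = TRUE)
  while (length(unique(spp)) < 2) spp <- sample(species, nl, replace = TRUE)
  leaves <- paste0(spp, "_", prefix, seq_len(nl))
  phy <- ape::rtree(nl)
  phy$tip.label <- sample(leaves)
  phy$edge.length <- NULL
  list(tree = phy, leaf_map = stats::setNames(spp, leaves), leaves = leaves)
}

# --- naive rooted reconciliation (second, independent postorder) -----------

# clade of species-tree tip indices below every node, via repeated expansion
naive_clades <- function(phy) {
  n <- ape::Ntip(phy)
  out <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) out[[i]] <- i
  repeat {
    done <- TRUE
    for (r in seq_len(nrow(phy$edge))) {
      a <- phy$edge[r, 1]; b <- phy$edge[r, 2]
      if (!is.null(out[[b]])) {
        merged <- sort(unique(c(out[[a]], out[[b]])))
        if (!identical(out[[a]], merged)) { out[[a]] <- merged; done <- FALSE }
      } else done <- FALSE
    }
    if (done) break
  }
  out
}

# naive LCA: smallest clade containing the given tip set
naive_lca <- function(stree, tipset, clades = naive_clades(stree)) {
  sizes <- vapply(clades, length, 0L)
  cand <- which(vapply(seq_along(clades), function(v)
    all(tipset %in% clades[[v]]), TRUE))
  cand[which.min(sizes[cand])]
}

# naive duplication/loss/deep-coalescence costs for a ROOTED gene tree
naive_rooted_costs <- function(gene_tree, species_tree, leaf_map) {
  cl <- naive_clades(species_tree)
  depth_of <- function(v) {
    d <- 0
    while (v != ape::Ntip(species_tree) + 1L) {
      v <- species_tree$edge[species_tree$edge[, 2] == v, 1]
      d <- d + 1
    }
    d
  }
  ng <- ape::Ntip(gene_tree)
  gcl <- naive_clades(gene_tree)
  tipset_of <- function(v) {
    labs <- gene_tree$tip.label[gcl[[v]]]
    match(unique(unname(leaf_map[labs])), species_tree$tip.label)
  }
  M <- vapply(seq_len(ng + gene_tree$Nnode), function(v)
    naive_lca(species_tree, tipset_of(v), cl), 0L)
  dups <- 0L; losses <- 0L
  for (g in (ng + 1L):(ng + gene_tree$Nnode)) {
    ch <- gene_tree$edge[gene_tree$edge[, 1] == g, 2]
    isdup <- any(M[ch] == M[g])
    if (isdup) dups <- dups + 1L
    for (c in ch)
      losses <- losses + depth_of(M[c]) - depth_of(M[g]) - (if (isdup) 0L else 1L)
  }
  # deep coalescences: count gene lineages crossing the top of each S branch
  nn <- ape::Ntip(species_tree) + species_tree$Nnode
  cnt <- integer(nn)
  parent_of <- function(v) species_tree$edge[species_tree$edge[, 2] == v, 1]
  for (r in seq_len(nrow(gene_tree$edge))) {
    g <- gene_tree$edge[r, 2]; pg <- gene_tree$edge[r, 1]
    s <- M[g]
    while (s != M[pg]) { cnt[s] <- cnt[s] + 1L; s <- parent_of(s) }
  }
  s <- M[ng + 1L]
  while (s != ape::Ntip(species_tree) + 1L) { cnt[s] <- cnt[s] + 1L; s <- parent_of(s) }
  ils <- sum(pmax(cnt[-(ape::Ntip(species_tree) + 1L)] - 1L, 0L))
  list(dups = dups, losses = losses, ils = ils)
}

# naive minimum over rootings: root the unrooted gene tree on every edge
# explicitly (via ape) and take the minima of the rooted costs
naive_min_over_roots <- function(gene_tree, species_tree, leaf_map) {
  fam_sp <- sort(unique(unname(leaf_map[gene_tree$tip.label])))
  st <- if (length(fam_sp) < ape::Ntip(species_tree))
    ape::keep.tip(species_tree, fam_sp) else species_tree
  ut <- ape::unroot(gene_tree)
  best <- NULL
  for (e in seq_len(nrow(ut$edge))) {
    rt <- rooted_at_edge(ut, e)
    rc <- naive_rooted_costs(rt, st, leaf_map)
    if (is.null(best)) best <- list(dl = rc$dups + rc$losses, d = rc$dups,
                                    l = rc$losses, ils = rc$ils)
    else {
      if (rc$dups + rc$losses < best$dl) {
        best$dl <- rc$dups + rc$losses; best$d <- rc$dups; best$l <- rc$losses
      }
      best$ils <- min(best$ils, rc$ils)
    }
  }
  best
}

# root an unrooted phylo on edge e (the root lands on that edge)
rooted_at_edge <- function(ut, e) {
  child <- ut$edge[e, 2]
  if (child <= ape::Ntip(ut))
    ape::root(ut, outgroup = child, resolve.root = TRUE)
  else
    ape::root(ut, node = child, resolve.root = TRUE)
}

# naive mulRF via the package-independent split listing in R
naive_mulrf <- function(gene_tree, species_tree, leaf_map) {
  fam_sp <- sort(unique(unname(leaf_map[gene_tree$tip.label])))
  st <- if (length(fam_sp) < ape::Ntip(species_tree))
    ape::keep.tip(species_tree, fam_sp) else species_tree
  copies <- table(unname(leaf_map[gene_tree$tip.label]))
  # extended species tree: replace each multi-copy species leaf by a star
  nwk <- ape::write.tree(st)
  for (sp in names(copies)) {
    if (copies[[sp]] > 1) {
      star <- paste0("(", paste0(sp, "..copy", seq_len(copies[[sp]]),
                                 collapse = ","), ")")
      nwk <- sub(paste0("(?<![A-Za-z0-9_.])", sp, "(?![A-Za-z0-9_.])"), star,
                 nwk, perl = TRUE)
    }
  }
  ext <- ape::read.tree(text = nwk)
  splitbag <- function(phy, map) {
    n <- ape::Ntip(phy)
    u <- ape::unroot(phy)
    cl <- naive_clades(u)
    keys <- character(0)
    for (v in seq_len(n + u$Nnode)) {
      if (v == n + 1L) next
      tips <- cl[[v]]
      if (length(tips) < 2L || n - length(tips) < 2L) next
      a <- sort(map[u$tip.label[tips]])
      b <- sort(map[u$tip.label[setdiff(seq_len(n), tips)]])
      ka <- paste(a, collapse = ","); kb <- paste(b, collapse = ",")
      keys <- c(keys, if (ka <= kb) paste(ka, kb, sep = "|") else paste(kb, ka, sep = "|"))
    }
    sort(keys)
  }
  gmap <- unname(leaf_map[gene_tree$tip.label]); names(gmap) <- gene_tree$tip.label
  emap <- sub("\\.\\.copy[0-9]+$", "", ext$tip.label); names(emap) <- ext$tip.label
  a <- splitbag(gene_tree, gmap)
  b <- splitbag(ext, emap)
  # multiset symmetric difference
  tab_a <- table(a); tab_b <- table(b)
  keys <- union(names(tab_a), names(tab_b))
  sum(vapply(keys, function(k) {
    abs((if (k %in% names(tab_a)) tab_a[[k]] else 0L) -
        (if (k %in% names(tab_b)) tab_b[[k]] else 0L))
  }, 0))
}

# tiny helper: unrooted topology equality
same_unrooted <- function(a, b) {
  identical(recsup:::topology_key(ape::unroot(a)), recsup:::topology_key(ape::unroot(b)))
}
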