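# Gene-tree/species-tree disagreement measures: LCA mapping, minimum
# duplications and losses, minimum deep coalescences -- each minimized over
# all gene-tree rootings -- and the mulRF distance for multi-labeled gene
# trees, plus the per-family distance scaling constants.

DIST_NAMES <- c("dups", "losses", "ils", "mulrf")

model_dist_idx <- function(model) {
  switch(model,
         DLIR = 0:3, DLI = 0:2, DL = 0:1, ILS = 2L,
         stop("unknown model: ", model))
}

# rooted phylo utilities shared by the R-level reconciliation operations
stree_tables <- function(species_tree) {
  n <- ape::Ntip(species_tree)
  nn <- n + species_tree$Nnode
  par <- integer(nn); par[] <- 0L
  for (r in seq_len(nrow(species_tree$edge)))
    par[species_tree$edge[r, 2L]] <- species_tree$edge[r, 1L]
  root <- n + 1L
  dep <- integer(nn)
  ord <- ape::reorder.phylo(species_tree, "postorder")$edge
  for (r in rev(seq_len(nrow(ord)))) dep[ord[r, 2L]] <- dep[ord[r, 1L]] + 1L
  list(n = n, par = par, dep = dep, root = root)
}

stree_lca <- function(tab, a, b) {
  while (a != b) {
    if (tab$dep[a] < tab$dep[b]) b <- tab$par[b] else a <- tab$par[a]
  }
  a
}

#' LCA mapping between a rooted gene tree and a rooted species tree
#'
#' Maps every gene-tree node `g` to the last common ancestor in the species
#' tree of the species below `g`.  Leaves map to their own species; internal
#' nodes map to the LCA of their children's images, which yields the most
#' parsimonious reconciliation.
#'
#' @param gene_tree rooted `phylo`.
#' @param species_tree rooted `phylo`.
#' @param leaf_map named character vector: gene leaf label -> species name.
#' @return integer vector indexed by gene-tree node number (ape numbering:
#'   tips first), holding species-tree node numbers.
#' @export
lca_map <- function(gene_tree, species_tree, leaf_map) {
  if (!ape::is.rooted(gene_tree) || !ape::is.rooted(species_tree))
    stop("both trees must be rooted")
  tab <- stree_tables(species_tree)
  ng <- ape::Ntip(gene_tree)
  M <- integer(ng + gene_tree$Nnode)
  sp <- unname(leaf_map[gene_tree$tip.label])
  if (anyNA(sp)) stop("leaf_map does not cover every gene-tree leaf")
  tipid <- match(sp, species_tree$tip.label)
  if (anyNA(tipid))
    stop("species missing from the species tree: ",
         paste(unique(sp[is.na(tipid)]), collapse = ", "))
  M[seq_len(ng)] <- tipid
  po <- ape::reorder.phylo(gene_tree, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    a <- po[r, 1L]; b <- po[r, 2L]
    M[a] <- if (M[a] == 0L) M[b] else stree_lca(tab, M[a], M[b])
  }
  M
}

#' Minimum duplications and losses of a rooted reconciliation
#'
#' Counts duplications (gene nodes whose LCA image equals a child's image)
#' and the matching minimal loss count from the LCA reconciliation: for each
#' child `c` of a gene node `g`, losses increase by the species-tree path
#' length from `M(g)` to `M(c)`, minus one per child when `g` is a
#' speciation.
#'
#' @inheritParams lca_map
#' @return named integer vector `c(duplications = , losses = )`.
#' @export
dup_loss <- function(gene_tree, species_tree, leaf_map) {
  M <- lca_map(gene_tree, species_tree, leaf_map)
  tab <- stree_tables(species_tree)
  ng <- ape::Ntip(gene_tree)
  kids <- vector("list", ng + gene_tree$Nnode)
  for (r in seq_len(nrow(gene_tree$edge))) {
    a <- gene_tree$edge[r, 1L]
    kids[[a]] <- c(kids[[a]], gene_tree$edge[r, 2L])
  }
  dups <- 0L; losses <- 0L
  for (g in (ng + 1L):(ng + gene_tree$Nnode)) {
    ch <- kids[[g]]
    isdup <- any(M[ch] == M[g])
    if (isdup) dups <- dups + 1L
    spec <- if (isdup) 0L else 1L
    for (c in ch) losses <- losses + (tab$dep[M[c]] - tab$dep[M[g]] - spec)
  }
  c(duplications = dups, losses = losses)
}

#' Minimum deep coalescences of a rooted reconciliation
#'
#' Counts extra lineages under the LCA embedding: for each species-tree
#' branch, the number of gene lineages crossing its top minus one, summed
#' over branches.  This equals the minimal deep-coalescence cost of making
#' the gene tree congruent with the species tree.
#'
#' @inheritParams lca_map
#' @return integer count.
#' @export
deep_coal <- function(gene_tree, species_tree, leaf_map) {
  M <- lca_map(gene_tree, species_tree, leaf_map)
  tab <- stree_tables(species_tree)
  cnt <- integer(tab$n + species_tree$Nnode)
  for (r in seq_len(nrow(gene_tree$edge))) {
    g <- gene_tree$edge[r, 2L]; pg <- gene_tree$edge[r, 1L]
    s <- M[g]
    while (s != M[pg]) { cnt[s] <- cnt[s] + 1L; s <- tab$par[s] }
  }
  ng <- ape::Ntip(gene_tree)
  s <- M[ng + 1L]
  while (s != tab$root) { cnt[s] <- cnt[s] + 1L; s <- tab$par[s] }
  sum(pmax(cnt[-tab$root] - 1L, 0L))
}

# shared marshalling: unrooted gene tree + restricted species tree -> kernel args
kernel_args <- function(gene_tree, species_tree, leaf_map, restrict = TRUE) {
  fam_sp <- sort(unique(unname(leaf_map[gene_tree$tip.label])))
  if (anyNA(fam_sp)) stop("leaf_map does not cover every gene-tree leaf")
  missing <- setdiff(fam_sp, species_tree$tip.label)
  if (length(missing))
    stop("species missing from the species tree: ", paste(missing, collapse = ", "))
  st <- species_tree
  if (restrict && length(fam_sp) < ape::Ntip(species_tree))
    st <- ape::keep.tip(species_tree, fam_sp)
  sp_order <- sort(st$tip.label)
  ut <- phylo_to_utree(gene_tree)
  spp <- match(unname(leaf_map[ut$leaves]), sp_order) - 1L
  list(sparent = phylo_to_parent(st, sp_order), edges = ut$edges,
       spp = as.integer(spp), species = sp_order, utree = ut)
}

#' Reconciliation costs minimized over all gene-tree rootings
#'
#' Roots the unrooted gene tree on every edge, evaluates the LCA
#' reconciliation, and reports duplications and losses at the rooting `r*`
#' that minimizes their sum, and deep coalescences at the (possibly
#' different) rooting `r**` that minimizes them.  Ties are broken by the
#' smallest edge index in the edge order of the unrooted tree
#' (`ape::unroot(gene_tree)$edge` row order).
#'
#' The species tree is always restricted to the species present in the gene
#' tree first (the model's convention; it also guarantees every species
#' branch carries at least one gene lineage).
#'
#' @param gene_tree unrooted (or arbitrarily rooted) `phylo`, at least 3 leaves.
#' @param species_tree rooted binary `phylo`.
#' @param leaf_map named character vector leaf -> species.
#' @return list with `dups`, `losses`, `ils`, `r_star`, `r_star2`.
#' @export
min_over_roots <- function(gene_tree, species_tree, leaf_map) {
  ka <- kernel_args(gene_tree, species_tree, leaf_map, restrict = TRUE)
  res <- cpp_distvec(ka$sparent, ka$edges, ka$spp, FALSE)
  list(dups = res$dups, losses = res$losses, ils = res$ils,
       r_star = res$r_star, r_star2 = res$r_star2)
}

#' mulRF distance between a multi-labeled gene tree and a species tree
#'
#' The species tree is restricted to the family's species, then extended so
#' that every species with `k > 1` gene copies becomes a `k`-furcation of
#' copy leaves; both trees are compared unrooted as multisets of nontrivial
#' species-multiset bipartitions, and the size of the symmetric difference is
#' returned.  The value does not depend on the rooting of either tree.
#'
#' @inheritParams min_over_roots
#' @return integer count.
#' @export
mulrf <- function(gene_tree, species_tree, leaf_map) {
  ka <- kernel_args(gene_tree, species_tree, leaf_map, restrict = TRUE)
  res <- cpp_distvec(ka$sparent, ka$edges, ka$spp, TRUE)
  res$mulrf
}

#' Disagreement vector between a gene tree and a species tree
#'
#' Computes the distance vector used by the hierarchical model: minimum
#' duplications and losses (at the optimal rooting `r*`), minimum deep
#' coalescences (at `r**`), and, under the DLIR parameterization, the mulRF
#' distance.  The species tree is restricted to the family's species before
#' any computation so unsampled species do not inflate loss counts.
#'
#' @inheritParams min_over_roots
#' @param model `"DLIR"` (four distances) or `"DLI"` (reconciliation
#'   distances only).
#' @return named numeric vector of class `distance_vector` with attributes
#'   `r_star` and `r_star2`.
#' @export
distance_vector <- function(gene_tree, species_tree, leaf_map, model = c("DLIR", "DLI")) {
  model <- match.arg(model)
  ka <- kernel_args(gene_tree, species_tree, leaf_map, restrict = TRUE)
  res <- cpp_distvec(ka$sparent, ka$edges, ka$spp, model == "DLIR")
  d <- c(dups = res$dups, losses = res$losses, ils = res$ils)
  if (model == "DLIR") d <- c(d, mulrf = res$mulrf)
  structure(d, r_star = res$r_star, r_star2 = res$r_star2, class = "distance_vector")
}

#' Distance scaling constants for a gene family
#'
#' The model standardizes every distance to a comparable scale via fixed
#' per-family constants: the duplication scale is `n - 1` (the maximum
#' possible number of duplications for `n` gene leaves), the mulRF scale is
#' an upper bound from the internal edge counts of the gene tree and of the
#' extended species tree, and the loss and deep-coalescence scales are the
#' empirical maxima of those distances over the input topologies against a
#' set of reference species trees (floored at 1).  Constants are fixed before
#' sampling and never updated.
#'
#' @param dist a [gene_tree_distribution()].
#' @param reference_trees list of rooted species trees used for the
#'   empirical maxima.
#' @param model `"DLIR"` or `"DLI"` (or `"DL"`/`"ILS"` for single-cost runs).
#' @return named numeric vector, one scale per distance in the model.
#' @export
scaling_constants <- function(dist, reference_trees, model = "DLIR") {
  idx <- model_dist_idx(model)
  fam <- dist$family
  nl <- length(fam$leaves)
  nsp <- length(fam$species)
  nmulti <- sum(table(unname(fam$leaf_species)) > 1L)
  maxes <- c(0, 0)
  if (nsp >= 2L) {
    sp_order <- fam$species
    edges <- lapply(dist$trees, function(t) phylo_to_utree(t, fam$leaves)$edges)
    spp <- match(unname(fam$leaf_species[fam$leaves]), sp_order) - 1L
    refs <- lapply(reference_trees, function(S) {
      st <- if (nsp < ape::Ntip(S)) ape::keep.tip(S, fam$species) else S
      phylo_to_parent(st, sp_order)
    })
    maxes <- cpp_scaling_maxes(edges, as.integer(spp), refs)
  }
  m <- c(max(1, nl - 1),
         max(1, maxes[1]),
         max(1, maxes[2]),
         max(1, (nl - 3) + max(nsp - 3, 0) + nmulti))
  stats::setNames(m[idx + 1L], DIST_NAMES[idx + 1L])
}
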