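# Summary-statistic coalescent species-tree baselines: GLASS, STEAC, SD and
# MAC, built from gene-wise species distance matrices.

#' Species distance matrix from one gene tree
#'
#' Entry (X, Y) is the minimum or the average of the path lengths between all
#' leaf pairs (x in X, y in Y).  In `lengths = "unit"` mode every branch is
#' set to length 1, so the entries are node-count path lengths (the
#' convention for topology-only inputs).
#'
#' @param tree `phylo` with branch lengths (any rooting).
#' @param leaf_map named character vector leaf -> species.
#' @param within `"min"` (GLASS/SD) or `"avg"` (STEAC/MAC).
#' @param lengths `"true"` to use the tree's branch lengths, `"unit"` for
#'   unit lengths.
#' @return symmetric numeric matrix with species row/col names; `NA` for
#'   species pairs absent from the gene.
#' @export
gene_distance_matrix <- function(tree, leaf_map, within = c("min", "avg"),
                                 lengths = c("true", "unit")) {
  within <- match.arg(within)
  lengths <- match.arg(lengths)
  if (lengths == "unit" || is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  D <- ape::cophenetic.phylo(tree)
  sp <- unname(leaf_map[tree$tip.label])
  if (anyNA(sp)) stop("leaf_map does not cover every leaf")
  species <- sort(unique(sp))
  k <- length(species)
  out <- matrix(NA_real_, k, k, dimnames = list(species, species))
  diag(out) <- 0
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    vals <- D[sp == species[a], sp == species[b], drop = FALSE]
    v <- if (within == "min") min(vals) else mean(vals)
    out[a, b] <- out[b, a] <- v
  }
  out
}

#' Merge gene-wise species distance matrices
#'
#' Combines per-gene matrices into one, taking for each species pair the
#' minimum (GLASS/MAC) or the mean (SD/STEAC) over the genes where the pair
#' is present.  A pair absent from every gene is an error (the species
#' cannot be placed).
#'
#' @param matrices list of matrices from [gene_distance_matrix()].
#' @param across `"min"` or `"mean"`.
#' @return merged symmetric matrix over the union of species.
#' @export
merge_matrices <- function(matrices, across = c("min", "mean")) {
  across <- match.arg(across)
  if (!length(matrices)) stop("no matrices to merge")
  species <- sort(unique(unlist(lapply(matrices, rownames))))
  k <- length(species)
  out <- matrix(NA_real_, k, k, dimnames = list(species, species))
  diag(out) <- 0
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    vals <- unlist(lapply(matrices, function(M) {
      if (species[a] %in% rownames(M) && species[b] %in% rownames(M))
        M[species[a], species[b]] else NA_real_
    }))
    vals <- vals[!is.na(vals)]
    if (!length(vals))
      stop("species pair (", species[a], ", ", species[b],
           ") absent from every gene")
    out[a, b] <- out[b, a] <- if (across == "min") min(vals) else mean(vals)
  }
  out
}

#' Agglomerative species tree from a distance matrix
#'
#' Deterministic single-linkage or UPGMA clustering with lexicographic
#' tie-breaking (among equally close cluster pairs, the pair whose smallest
#' member labels sort first is merged), producing an ultrametric rooted
#' tree with node heights at half the merge distance.
#'
#' @param D complete symmetric distance matrix with species names.
#' @param method `"upgma"` (mean linkage) or `"single_linkage"`.
#' @return rooted `phylo`.
#' @export
build_species_tree <- function(D, method = c("upgma", "single_linkage")) {
  method <- match.arg(method)
  if (any(is.na(D))) stop("distance matrix has missing entries")
  labs <- rownames(D)
  k <- length(labs)
  if (k < 2L) stop("need at least two species")
  clusters <- lapply(labs, function(x) x)       # member labels
  nwk <- as.list(labs)                          # newick fragment per cluster
  hgt <- rep(0, k)                              # current height per cluster
  size <- rep(1L, k)
  d <- D
  active <- seq_len(k)
  while (length(active) > 1L) {
    best <- NULL; bestval <- Inf; bestkey <- NULL
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      a <- active[ii]; b <- active[jj]
      v <- d[a, b]
      key <- paste(sort(c(min(clusters[[a]]), min(clusters[[b]]))), collapse = "\r")
      if (v < bestval - 1e-12 ||
          (abs(v - bestval) <= 1e-12 && (is.null(bestkey) || key < bestkey))) {
        bestval <- v; best <- c(a, b); bestkey <- key
      }
    }
    a <- best[1L]; b <- best[2L]
    h <- bestval / 2
    newn <- paste0("(", nwk[[a]], ":", format(max(h - hgt[a], 0), digits = 10),
                   ",", nwk[[b]], ":", format(max(h - hgt[b], 0), digits = 10), ")")
    # linkage update against the remaining clusters
    for (cids in setdiff(active, c(a, b))) {
      v <- if (method == "single_linkage") min(d[a, cids], d[b, cids])
           else (d[a, cids] * size[a] + d[b, cids] * size[b]) / (size[a] + size[b])
      d[a, cids] <- d[cids, a] <- v
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    nwk[[a]] <- newn
    hgt[a] <- h
    size[a] <- size[a] + size[b]
    active <- setdiff(active, b)
  }
  ape::read.tree(text = paste0(nwk[[active]], ";"))
}

#' Distance-matrix species-tree methods (GLASS, STEAC, SD, MAC)
#'
#' Composes the three stages with each method's conventions:
#' GLASS = (min within, min across, single linkage);
#' SD = (min within, mean across, UPGMA);
#' STEAC = (avg within, mean across, UPGMA);
#' MAC = (avg within, min across, single linkage).
#'
#' @param trees list of gene trees (`phylo`), one per family.
#' @param leaf_maps list of named leaf -> species maps, one per tree (a
#'   single shared map is recycled).
#' @param method one of `"GLASS"`, `"STEAC"`, `"SD"`, `"MAC"`.
#' @param lengths `"true"` or `"unit"` (see [gene_distance_matrix()]).
#' @return rooted `phylo` species-tree estimate.
#' @export
run_distance_method <- function(trees, leaf_maps, method = c("GLASS", "STEAC", "SD", "MAC"),
                                lengths = c("true", "unit")) {
  method <- match.arg(method)
  lengths <- match.arg(lengths)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.list(leaf_maps)) leaf_maps <- list(leaf_maps)
  if (length(leaf_maps) == 1L) leaf_maps <- rep(leaf_maps, length(trees))
  disp <- switch(method,
                 GLASS = list(within = "min", across = "min", link = "single_linkage"),
                 SD    = list(within = "min", across = "mean", link = "upgma"),
                 STEAC = list(within = "avg", across = "mean", link = "upgma"),
                 MAC   = list(within = "avg", across = "min", link = "single_linkage"))
  mats <- lapply(seq_along(trees), function(i)
    gene_distance_matrix(trees[[i]], leaf_maps[[i]], within = disp$within,
                         lengths = lengths))
  M <- merge_matrices(mats, across = disp$across)
  build_species_tree(M, method = disp$link)
}
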