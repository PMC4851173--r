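# Three-tree simulator: species tree (Kingman coalescent or Yule), birth-
# death locus trees inside the species tree, and multispecies-coalescent
# gene trees inside each locus tree, with gamma rate-heterogeneity
# multipliers at all three levels.

#' Simulate a species tree
#'
#' Generates an ultrametric rooted species tree under the Kingman coalescent
#' or a pure-birth (Yule) process and rescales it to the requested
#' root-to-tip height in generations.  Coalescent-unit branch lengths are
#' `generations / (2 Ne)`.
#'
#' @param n number of species (at least 3).
#' @param mode `"coalescent"` or `"yule"`.
#' @param height_generations root-to-tip height in generations; `NULL` keeps
#'   the natural coalescent scale (`2 Ne` generations per coalescent unit).
#' @param Ne effective population size (diploid-style convention: one
#'   coalescent unit is `2 Ne` generations).
#' @param labels optional species names (default `s01`, `s02`, ...).
#' @return rooted ultrametric `phylo`, branch lengths in generations, with
#'   attributes `Ne` and `height_generations`.
#' @export
sim_species_tree <- function(n, mode = c("coalescent", "yule"),
                             height_generations = NULL, Ne = 2000,
                             labels = NULL) {
  mode <- match.arg(mode)
  if (n < 3) stop("need at least 3 species")
  if (is.null(labels)) labels <- sprintf("s%02d", seq_len(n))
  phy <- if (mode == "coalescent") ape::rcoal(n, tip.label = labels)
         else { t <- ape::rphylo(n, birth = 1, death = 0); t$tip.label <- labels; t }
  ht <- max(ape::node.depth.edgelength(phy))
  if (!is.null(height_generations)) {
    phy$edge.length <- phy$edge.length * height_generations / ht
  } else {
    # rcoal times are in units of 2N generations already
    phy$edge.length <- phy$edge.length * 2 * Ne
  }
  attr(phy, "Ne") <- Ne
  attr(phy, "height_generations") <- max(ape::node.depth.edgelength(phy))
  phy
}

#' Coalescent-unit version of a species tree
#'
#' @param species_tree `phylo` with branch lengths in generations.
#' @param Ne effective population size (defaults to the tree's attribute).
#' @return `phylo` with branch lengths in coalescent units
#'   (`generations / (2 Ne)`).
#' @export
species_tree_coalescent <- function(species_tree, Ne = attr(species_tree, "Ne")) {
  if (is.null(Ne)) stop("Ne not given and not stored on the tree")
  species_tree$edge.length <- species_tree$edge.length / (2 * Ne)
  species_tree
}

# --- internal node-record machinery -----------------------------------------
# A record is list(type, len, sp, h, label, children); `len` is the branch
# length above the node, `sp` the id of the containing branch of the parent
# tree (species tree for locus nodes, locus tree for gene nodes).

record_to_phylo <- function(rec) {
  count <- function(r) if (is.null(r$children)) 1L else sum(vapply(r$children, count, 0L))
  m <- count(rec)
  env <- new.env()
  env$tip <- 0L; env$int <- m + 1L
  env$edge <- matrix(0L, 0, 2); env$elen <- numeric(0)
  env$type <- character(2L * m - 1L); env$branch <- integer(2L * m - 1L)
  env$labels <- character(m)
  assign_ids <- function(r) {
    if (is.null(r$children)) {
      env$tip <- env$tip + 1L
      id <- env$tip
      env$labels[id] <- r$label
    } else {
      id <- env$int
      env$int <- env$int + 1L
      for (ch in r$children) {
        cid <- assign_ids(ch)
        env$edge <- rbind(env$edge, c(id, cid))
        env$elen <- c(env$elen, ch$len)
      }
    }
    env$type[id] <- r$type
    env$branch[id] <- if (is.null(r$sp)) NA_integer_ else r$sp
    id
  }
  assign_ids(rec)
  phy <- structure(list(edge = env$edge, edge.length = env$elen,
                        tip.label = env$labels, Nnode = m - 1L),
                   class = "phylo", order = "cladewise")
  attr(phy, "node_type") <- env$type
  attr(phy, "node_branch") <- env$branch
  phy
}

#' Simulate a locus tree inside a species tree
#'
#' Grows a birth-death process of (paralogous) loci along the species-tree
#' branches: a single locus enters at the root, duplicates at rate `birth`
#' and dies at rate `death` (per locus per generation); lineages split at
#' speciation nodes and extinct loci are pruned.  Leaves are labeled
#' `<species>_<locus>`.
#'
#' @param species_tree rooted `phylo` with branch lengths in generations.
#' @param birth duplication rate per generation.
#' @param death loss rate per generation (the simulation design keeps
#'   `death <= 0.75 * birth` at parameter sampling; larger values are allowed
#'   here).
#' @param min_species resimulate until at least this many species carry a
#'   surviving locus (`0` disables; fully extinct families always retry up
#'   to `max_tries`).
#' @param max_tries retry guard.
#' @return a `phylo` with attributes `node_type` (`"dup"`, `"spec"`,
#'   `"leaf"`) and `node_branch` (containing species-tree node, ape
#'   numbering), or `NULL` if every attempt went extinct.
#' @export
sim_locus_tree <- function(species_tree, birth, death, min_species = 2L,
                           max_tries = 100L) {
  n <- ape::Ntip(species_tree)
  kids <- vector("list", n + species_tree$Nnode)
  blen <- numeric(n + species_tree$Nnode)
  for (r in seq_len(nrow(species_tree$edge))) {
    a <- species_tree$edge[r, 1L]; b <- species_tree$edge[r, 2L]
    kids[[a]] <- c(kids[[a]], b)
    blen[b] <- species_tree$edge.length[r]
  }
  rate <- birth + death
  sim_lineage <- function(v, remaining) {
    w <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (w < remaining) {
      if (stats::runif(1) < birth / rate) {
        c1 <- sim_lineage(v, remaining - w)
        c2 <- sim_lineage(v, remaining - w)
        if (is.null(c1) && is.null(c2)) return(NULL)
        if (is.null(c1) || is.null(c2)) {
          ch <- if (is.null(c1)) c2 else c1
          ch$len <- ch$len + w
          return(ch)
        }
        return(list(type = "dup", len = w, sp = v, children = list(c1, c2)))
      }
      return(NULL)  # loss
    }
    if (is.null(kids[[v]])) {
      return(list(type = "leaf", len = remaining, sp = v,
                  label = species_tree$tip.label[v]))
    }
    ch <- lapply(kids[[v]], function(d) sim_lineage(d, blen[d]))
    alive <- !vapply(ch, is.null, TRUE)
    if (!any(alive)) return(NULL)
    if (sum(alive) == 1L) {
      c1 <- ch[alive][[1L]]
      c1$len <- c1$len + remaining
      return(c1)
    }
    list(type = "spec", len = remaining, sp = v, children = ch[alive])
  }
  for (try in seq_len(max_tries)) {
    rec <- sim_lineage(n + 1L, 0)
    if (is.null(rec)) next
    # label loci per species and count species present
    cnt <- new.env(); spp <- character(0)
    relabel <- function(r) {
      if (is.null(r$children)) {
        k <- if (is.null(cnt[[r$label]])) 1L else cnt[[r$label]] + 1L
        cnt[[r$label]] <- k
        spp <<- c(spp, r$label)
        r$label <- paste0(r$label, "_", k)
      } else r$children <- lapply(r$children, relabel)
      r
    }
    rec <- relabel(rec)
    if (length(unique(spp)) < min_species) next
    if (is.null(rec$children)) next  # single surviving locus: no tree
    rec$len <- 0
    return(record_to_phylo(rec))
  }
  NULL
}

#' Simulate a gene tree by the multispecies coalescent inside a locus tree
#'
#' Starts `individuals` gene lineages at every locus-tree leaf and coalesces
#' them backwards in time at rate `choose(k, 2) / (2 Ne)` per generation
#' within each locus branch; lineages that fail to coalesce exit into the
#' parent branch, and the process completes above the root.  Leaves are
#' labeled `<species>_<locus>_i<individual>`.
#'
#' @param locus_tree ultrametric `phylo` in generations (from
#'   [sim_locus_tree()]; a plain species tree also works, which yields the
#'   standard multispecies coalescent without paralogy).
#' @param Ne effective population size.
#' @param individuals gene copies sampled per locus leaf.
#' @return rooted binary `phylo` in generations with attribute
#'   `node_branch` (containing locus-tree node per gene node).
#' @export
sim_gene_tree <- function(locus_tree, Ne, individuals = 1L) {
  if (individuals < 1L) stop("need at least one individual")
  m <- ape::Ntip(locus_tree)
  nn <- m + locus_tree$Nnode
  kids <- vector("list", nn)
  for (r in seq_len(nrow(locus_tree$edge))) {
    a <- locus_tree$edge[r, 1L]
    kids[[a]] <- c(kids[[a]], locus_tree$edge[r, 2L])
  }
  depth <- ape::node.depth.edgelength(locus_tree)
  H <- max(depth)
  height <- H - depth  # time before present per locus node
  coalesce_along <- function(lin, t_lo, t_hi, branch) {
    h <- t_lo
    while (length(lin) >= 2L) {
      k <- length(lin)
      h <- h + stats::rexp(1, rate = k * (k - 1) / 2 / (2 * Ne))
      if (h > t_hi) break
      pair <- sample.int(k, 2L)
      a <- lin[[pair[1L]]]; b <- lin[[pair[2L]]]
      a$rec$len <- h - a$h; b$rec$len <- h - b$h
      newrec <- list(type = "coal", len = 0, sp = branch,
                     children = list(a$rec, b$rec))
      lin <- c(lin[-pair], list(list(rec = newrec, h = h)))
    }
    lin
  }
  walk <- function(v) {
    if (is.null(kids[[v]])) {
      lin <- lapply(seq_len(individuals), function(i)
        list(rec = list(type = "leaf", len = 0, sp = v,
                        label = paste0(locus_tree$tip.label[v], "_i", i)),
             h = height[v]))
    } else {
      lin <- unlist(lapply(kids[[v]], walk), recursive = FALSE)
    }
    t_hi <- if (v == m + 1L) Inf else height[locus_tree$edge[locus_tree$edge[, 2L] == v, 1L][1L]]
    coalesce_along(lin, height[v], t_hi, v)
  }
  out <- walk(m + 1L)
  stopifnot(length(out) == 1L)
  rec <- out[[1L]]$rec
  rec$len <- 0
  record_to_phylo(rec)
}

#' Apply gamma rate heterogeneity to a tree
#'
#' Multiplies every branch by an independent Gamma(shape, rate = shape) draw
#' (mean 1) and by the substitution rate, converting generation-scale branch
#' lengths into expected substitutions.  The result is generally
#' non-clocklike.
#'
#' @param tree a `phylo`.
#' @param gamma_shape positive shape (rate is set to the shape so the
#'   multiplier mean is 1; large shapes approach a strict clock).
#' @param subst_rate substitutions per time unit.
#' @param multipliers optional fixed per-branch multipliers (recycled),
#'   bypassing the gamma draws.
#' @return the tree with rescaled `edge.length` and attribute
#'   `rate_multipliers`.
#' @export
apply_rate_heterogeneity <- function(tree, gamma_shape = 1, subst_rate = 1,
                                     multipliers = NULL) {
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  ne <- length(tree$edge.length)
  if (is.null(multipliers))
    multipliers <- stats::rgamma(ne, shape = gamma_shape, rate = gamma_shape)
  multipliers <- rep_len(multipliers, ne)
  tree$edge.length <- tree$edge.length * multipliers * subst_rate
  attr(tree, "rate_multipliers") <- multipliers
  tree
}

#' Simulation parameter laws
#'
#' Bundles the sampling distributions of the simulation study; every
#' argument can be overridden for scaled-down designs.  Defaults: species
#' count Uniform(10, 80); root height Uniform(1e2, 1e4) generations;
#' expected duplications per family Uniform(1e-3, 4); family count
#' Uniform(2, 50); duplication rate Exponential with mean `Edup / sigma`
#' (`sigma` = total species-tree length in generations); loss rate
#' Uniform(0, 0.75 beta); `Ne = 2000 LogNormal(0, 0.25)`; individuals per
#' species Uniform(1, 10), shared by all families; substitution rate 0.001
#' per generation; Gamma(1, 1) rate multipliers at the species, locus and
#' gene levels.
#'
#' @param n_species_range,height_range,edup_range,n_families_range,individuals_range
#'   bounds of the respective uniform laws (counts are discrete).
#' @param ne_base,ne_lnorm_sd log-normal effective-population-size law.
#' @param subst_rate substitution rate per generation.
#' @param gamma_shape shape of all three rate-multiplier laws.
#' @param loss_factor upper bound of the loss rate as a fraction of the
#'   duplication rate.
#' @param species_tree_mode `"coalescent"` or `"yule"`.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_species_range = c(10L, 80L),
                       height_range = c(100, 10000),
                       edup_range = c(1e-3, 4),
                       n_families_range = c(2L, 50L),
                       individuals_range = c(1L, 10L),
                       ne_base = 2000, ne_lnorm_sd = 0.25,
                       subst_rate = 0.001, gamma_shape = 1,
                       loss_factor = 0.75,
                       species_tree_mode = "coalescent") {
  structure(as.list(environment()), class = "sim_params")
}

runif_int <- function(range) {
  v <- seq(range[1L], range[2L])
  if (length(v) == 1L) v else sample(v, 1L)
}

#' Simulate one replicate data set
#'
#' Draws every parameter from the laws in `params`, then runs the three-tree
#' cascade: species tree, one birth-death locus tree per gene family, one
#' multispecies-coalescent gene tree per locus tree, and substitution-unit
#' branch lengths via hierarchically composed gamma rate multipliers
#' (species x locus x gene level).  All drawn values are kept in the
#' `provenance` element so a replicate is fully reproducible from its seed.
#'
#' @param params a [sim_params()].
#' @return object of class `sim_replicate`: `species_tree` (generations),
#'   `species_tree_coal` (coalescent units), `species` names, `Ne`,
#'   `families` (list with `locus_tree`, `gene_tree` in generations,
#'   `gene_tree_subst` in substitution units, and a [gene_family()]), and
#'   `provenance`.
#' @export
sim_replicate <- function(params = sim_params()) {
  p <- params
  n_sp <- runif_int(p$n_species_range)
  height <- stats::runif(1, p$height_range[1L], p$height_range[2L])
  # the population-size law is read as the number of gene copies (2 Ne): with
  # root heights of 1e2-1e4 generations this pins the species-tree height to
  # the intended 0.05-5 coalescent-unit design window
  Ne <- p$ne_base / 2 * stats::rlnorm(1, 0, p$ne_lnorm_sd)
  edup <- stats::runif(1, p$edup_range[1L], p$edup_range[2L])
  n_fam <- runif_int(p$n_families_range)
  individuals <- runif_int(p$individuals_range)
  stree <- sim_species_tree(n_sp, mode = p$species_tree_mode,
                            height_generations = height, Ne = Ne)
  sigma <- sum(stree$edge.length)
  hs <- stats::rgamma(nrow(stree$edge), p$gamma_shape, p$gamma_shape)
  hs_node <- numeric(ape::Ntip(stree) + stree$Nnode)
  hs_node[stree$edge[, 2L]] <- hs
  hs_node[ape::Ntip(stree) + 1L] <- 1
  fams <- list()
  prov_fam <- list()
  i <- 1L
  while (i <= n_fam) {
    beta <- stats::rexp(1, rate = sigma / edup)
    loss <- stats::runif(1, 0, p$loss_factor * beta)
    ltree <- sim_locus_tree(stree, beta, loss)
    if (is.null(ltree)) next
    gtree <- sim_gene_tree(ltree, Ne, individuals)
    # hierarchical rate multipliers: species -> locus -> gene
    lbr <- attr(ltree, "node_branch")
    hl_node <- numeric(length(lbr))
    hl <- stats::rgamma(nrow(ltree$edge), p$gamma_shape, p$gamma_shape)
    for (r in seq_len(nrow(ltree$edge))) {
      ch <- ltree$edge[r, 2L]
      hl_node[ch] <- hl[r] * hs_node[lbr[ch]]
    }
    hl_node[ape::Ntip(ltree) + 1L] <- hs_node[lbr[ape::Ntip(ltree) + 1L]]
    gbr <- attr(gtree, "node_branch")
    hg <- stats::rgamma(nrow(gtree$edge), p$gamma_shape, p$gamma_shape)
    gmult <- numeric(nrow(gtree$edge))
    for (r in seq_len(nrow(gtree$edge))) {
      ch <- gtree$edge[r, 2L]
      gmult[r] <- hg[r] * hl_node[gbr[ch]]
    }
    gsub <- apply_rate_heterogeneity(gtree, p$gamma_shape, p$subst_rate,
                                     multipliers = gmult)
    fam <- gene_family(i, gsub$tip.label, stree$tip.label)
    fams[[i]] <- list(locus_tree = ltree, gene_tree = gtree,
                      gene_tree_subst = gsub, family = fam)
    prov_fam[[i]] <- list(beta = beta, loss = loss,
                          n_leaves = ape::Ntip(gtree),
                          n_species = length(fam$species))
    i <- i + 1L
  }
  structure(list(species_tree = stree,
                 species_tree_coal = species_tree_coalescent(stree, Ne),
                 species = stree$tip.label, Ne = Ne, families = fams,
                 provenance = list(n_species = n_sp, height = height, Ne = Ne,
                                   edup = edup, n_families = n_fam,
                                   individuals = individuals, sigma = sigma,
                                   sigma_coal = sigma / (2 * Ne),
                                   families = prov_fam)),
            class = "sim_replicate")
}

#' Write a replicate to a directory
#'
#' Emits `species.nwk` (generations), `species_coal.nwk` (coalescent units),
#' `species_list.txt`, per-family `genefam_XXX.nwk` (substitution-unit true
#' gene trees) and a `params.json` provenance record.
#'
#' @param rep a [sim_replicate()].
#' @param dir output directory (created if needed).
#' @export
write_replicate <- function(rep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(rep$species_tree, file.path(dir, "species.nwk"))
  ape::write.tree(rep$species_tree_coal, file.path(dir, "species_coal.nwk"))
  writeLines(rep$species, file.path(dir, "species_list.txt"))
  for (i in seq_along(rep$families))
    ape::write.tree(rep$families[[i]]$gene_tree_subst,
                    file.path(dir, sprintf("genefam_%03d.nwk", i)))
  jsonlite::write_json(rep$provenance, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
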