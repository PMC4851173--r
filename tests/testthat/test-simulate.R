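# Three-tree simulator: species trees, birth-death locus trees,
# multispecies-coalescent gene trees, rate heterogeneity, full replicates.

test_that("species trees are ultrametric with the requested height", {
  set.seed(41)
  for (mode in c("coalescent", "yule")) {
    st <- sim_species_tree(6, mode, height_generations = 5000, Ne = 1000)
    expect_equal(ape::Ntip(st), 6L)
    expect_true(ape::is.binary(st) && ape::is.rooted(st))
    depths <- ape::node.depth.edgelength(st)[1:6]
    expect_equal(max(depths), 5000)
    expect_true(all(abs(depths - 5000) < 1e-6))  # ultrametric
  }
  st3 <- sim_species_tree(3, "coalescent", height_generations = 100, Ne = 10)
  expect_equal(st3$Nnode, 2L)
  coal <- species_tree_coalescent(st3)
  expect_equal(sum(coal$edge.length) * 2 * attr(st3, "Ne"), sum(st3$edge.length))
})

test_that("pairwise coalescence times average 2Ne generations", {
  set.seed(43)
  Ne <- 500
  times <- replicate(600, {
    lt <- ape::read.tree(text = "(A:0.0001,B:0.0001);")
    g <- sim_gene_tree(lt, Ne = Ne, individuals = 1)
    max(ape::node.depth.edgelength(g))
  })
  expect_equal(mean(times), 2 * Ne, tolerance = 0.15)
})

test_that("locus trees follow the birth-death bookkeeping", {
  set.seed(47)
  st <- sim_species_tree(5, "coalescent", height_generations = 2000, Ne = 500)
  # no duplication, no loss: locus tree is the species tree
  lt0 <- sim_locus_tree(st, birth = 0, death = 0)
  expect_equal(sort(lt0$tip.label), sort(paste0(st$tip.label, "_1")))
  lt0r <- lt0; lt0r$tip.label <- sub("_1$", "", lt0r$tip.label)
  expect_true(same_unrooted(lt0r, st))
  # a duplication happens inside one species branch: both child lineages
  # start there, so the child nodes' branches lie in that branch's subtree
  lt <- NULL
  while (is.null(lt) || !any(attr(lt, "node_type") == "dup"))
    lt <- sim_locus_tree(st, birth = 5e-4, death = 0)
  ty <- attr(lt, "node_type"); br <- attr(lt, "node_branch")
  desc <- function(v) {
    out <- v
    repeat {
      ch <- st$edge[st$edge[, 1] %in% out, 2]
      new <- union(out, ch)
      if (length(new) == length(out)) return(out)
      out <- new
    }
  }
  for (v in which(ty == "dup")) {
    ch <- lt$edge[lt$edge[, 1] == v, 2]
    expect_true(all(br[ch] %in% desc(br[v])))
  }
  # death = 0: mean duplication count tracks birth x total lineage length
  set.seed(49)
  b <- 2e-5
  sigma <- sum(st$edge.length)
  ndup <- replicate(300, {
    l <- sim_locus_tree(st, birth = b, death = 0)
    sum(attr(l, "node_type") == "dup")
  })
  expect_equal(mean(ndup), b * sigma, tolerance = 0.25)
})

test_that("gene trees are binary, rooted, positive-length and labeled by locus", {
  set.seed(53)
  st <- sim_species_tree(4, "coalescent", height_generations = 3000, Ne = 300)
  lt <- sim_locus_tree(st, birth = 3e-4, death = 1e-4)
  g <- sim_gene_tree(lt, Ne = 300, individuals = 3)
  expect_true(ape::is.binary(g) && ape::is.rooted(g))
  expect_equal(ape::Ntip(g), 3L * ape::Ntip(lt))
  expect_true(all(g$edge.length >= 0))
  expect_true(all(grepl("_i[0-9]+$", g$tip.label)))
  # leaf species are recoverable by substring mapping
  m <- map_leaves_to_species(g$tip.label, st$tip.label)
  expect_setequal(unique(unname(m)), unique(sub("_.*", "", lt$tip.label)))
})

test_that("3-taxon discordance follows (2/3) exp(-t) on a small grid", {
  set.seed(59)
  Ne <- 400
  disc <- function(tcoal, n) {
    s <- ape::read.tree(text = sprintf("((A:100,B:100):%f,C:%f);",
                                       tcoal * 2 * Ne, 100 + tcoal * 2 * Ne))
    ref <- recsup:::rooted_key(ape::read.tree(text = "((A_i1,B_i1),C_i1);"))
    bad <- 0L
    for (i in seq_len(n))
      bad <- bad + !identical(ref, recsup:::rooted_key(sim_gene_tree(s, Ne, 1)))
    bad / n
  }
  for (t in c(0.2, 1)) {
    expected <- 2 / 3 * exp(-t)
    n <- 800
    obs <- disc(t, n)
    expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / n) + 1e-9)
  }
})

test_that("rate heterogeneity preserves expected length and breaks the clock", {
  set.seed(61)
  st <- sim_species_tree(6, "coalescent", height_generations = 1000, Ne = 100)
  tot <- replicate(300, sum(apply_rate_heterogeneity(st, 1, 1)$edge.length))
  expect_equal(mean(tot), sum(st$edge.length), tolerance = 0.1)
  het <- apply_rate_heterogeneity(st, 1, 1)
  d <- ape::node.depth.edgelength(het)[1:6]
  expect_gt(stats::sd(d), 0)
  # degenerate gamma (huge shape): effectively clocklike
  het2 <- apply_rate_heterogeneity(st, 1e6, 1)
  d2 <- ape::node.depth.edgelength(het2)[1:6]
  expect_lt(stats::sd(d2) / mean(d2), 0.01)
  # multipliers independent across branches
  ms <- t(replicate(200, attr(apply_rate_heterogeneity(st, 1, 1), "rate_multipliers")))
  cors <- stats::cor(ms)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.25)
  expect_error(apply_rate_heterogeneity(st, 0), "positive")
})

test_that("replicates draw coherent parameters and are seed-reproducible", {
  p <- sim_params(n_species_range = c(5, 7), n_families_range = c(2, 3),
                  individuals_range = c(1, 2))
  set.seed(67); r1 <- sim_replicate(p)
  set.seed(67); r2 <- sim_replicate(p)
  expect_identical(r1$provenance, r2$provenance)
  expect_identical(ape::write.tree(r1$families[[1]]$gene_tree_subst),
                   ape::write.tree(r2$families[[1]]$gene_tree_subst))
  pv <- r1$provenance
  expect_true(pv$n_species >= 5 && pv$n_species <= 7)
  expect_true(pv$n_families >= 2 && pv$n_families <= 3)
  expect_length(r1$families, pv$n_families)
  for (f in r1$families) {
    expect_true(all(f$family$species %in% r1$species))
    expect_true(ape::is.binary(f$gene_tree))
    # loss rate bounded by 0.75 x duplication rate at sampling
  }
  for (pf in pv$families) expect_lte(pf$loss, 0.75 * pf$beta)
  # forced Edup ~ 0 gives (near-)single-copy families
  p0 <- sim_params(n_species_range = c(5, 5), n_families_range = c(3, 3),
                   edup_range = c(1e-9, 1e-8))
  set.seed(71)
  r0 <- sim_replicate(p0)
  for (f in r0$families)
    expect_true(all(table(unname(f$family$leaf_species)) ==
                    r0$provenance$individuals))
})

test_that("replicate directories round-trip through the text formats", {
  set.seed(73)
  p <- sim_params(n_species_range = c(5, 5), n_families_range = c(2, 2))
  rep <- sim_replicate(p)
  d <- withr::local_tempdir()
  write_replicate(rep, d)
  expect_true(file.exists(file.path(d, "species.nwk")))
  sp <- read_species_list(file.path(d, "species_list.txt"))
  expect_setequal(sp, rep$species)
  st <- ape::read.tree(file.path(d, "species.nwk"))
  expect_true(same_unrooted(st, rep$species_tree))
  pj <- jsonlite::read_json(file.path(d, "params.json"))
  expect_equal(pj$n_species, rep$provenance$n_species)
})
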