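# Hierarchical model components and the brute-force partition function.

test_that("unscaled log density is the scaled negative distance sum", {
  expect_equal(unscaled_log_density(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(unscaled_log_density(2, 1, 1), -2)
  expect_equal(unscaled_log_density(c(1, 3, 1), c(0.5, 1, 2), c(1, 1, 1)), -5.5)
  expect_error(unscaled_log_density(1, 0, 1), "positive")
  expect_error(unscaled_log_density(1, c(1, 1), 1), "length")
})

test_that("penalty priors are exponential log densities", {
  expect_equal(log_prior_lambda(1, 1), -1)
  expect_equal(log_prior_lambda(1e-12, 2), -1e-12 / 2 - log(2))
  expect_equal(log_prior_lambda(2, 0.5), -4 - log(0.5))
  expect_error(log_prior_lambda(-1, 1), "positive")
  expect_equal(log_prior_lambda0(1, 1), -1)
  expect_equal(log_prior_lambda0(3, 2), -1.5 - log(2))
})

test_that("species prior counts rooted labeled topologies", {
  expect_equal(log_species_prior(3), -log(3))
  expect_equal(log_species_prior(4), -log(15))
  expect_equal(log_species_prior(5), -log(105))
  expect_error(log_species_prior(2), "at least 3")
})

test_that("log joint adds its parts and doubles with duplicated families", {
  species <- c("A", "B", "C", "D")
  S <- ape::read.tree(text = "((A,B),(C,D));")
  fam <- gene_family(1, c("A_1", "B_1", "C_1", "D_1"), species)
  d <- gene_tree_distribution(fam, ape::read.tree(text = "((A_1,B_1),(C_1,D_1));"))
  m <- list(rep(1, 4))
  lam <- matrix(1, 1, 4); lam0 <- rep(1, 4)
  lj <- log_joint(S, list(d), 1L, lam, lam0, m, hyper_mean = 1, model = "DLIR")
  # zero distances; log g = log 1 = 0; priors: 4 x (-1) each level; prior on S
  expect_equal(lj, -4 - 4 - log(15))
  lj2 <- log_joint(S, list(d, d), c(1L, 1L), rbind(lam, lam), lam0,
                   c(m, m), hyper_mean = 1, model = "DLIR")
  expect_equal(lj2 - (-4 - log(15)), 2 * (lj - (-4 - log(15))))
  # order invariance with heterogeneous families
  d2 <- gene_tree_distribution(fam, list(
    ape::read.tree(text = "((A_1,C_1),(B_1,D_1));"),
    ape::read.tree(text = "((A_1,B_1),(C_1,D_1));")), c(0.4, 0.6))
  lamh <- matrix(c(0.5, 1, 2, 1, 1, 1, 0.3, 2), 2, 4, byrow = TRUE)
  mh <- list(rep(1, 4), rep(2, 4))
  a <- log_joint(S, list(d, d2), c(1L, 1L), lamh, lam0, mh, 1, "DLIR")
  b <- log_joint(S, list(d2, d), c(1L, 1L), lamh[2:1, ], lam0, mh[2:1], 1, "DLIR")
  expect_equal(a, b)
})

test_that("log joint agrees with independent term-by-term recomputation", {
  set.seed(37)
  species <- paste0("S", 1:5)
  S <- rand_stree(species)
  dists <- lapply(1:3, function(i) {
    g <- rand_gene(species, 5, prefix = paste0("f", i))
    fam <- gene_family(i, g$leaves, species, leaf_map = g$leaf_map)
    g2 <- rand_gene(species, 5, prefix = paste0("f", i))
    # same leaves, different topology: rebuild on the same labels
    t2 <- ape::rtree(5); t2$tip.label <- sample(g$leaves); t2$edge.length <- NULL
    gene_tree_distribution(fam, list(g$tree, t2), c(0.6, 0.4))
  })
  lam <- matrix(runif(9, 0.2, 2), 3, 3)
  lam0 <- runif(3, 0.5, 2)
  m <- lapply(dists, function(d) runif(3, 1, 5))
  gi <- c(1L, 2L, 1L)
  lj <- log_joint(S, dists, gi, lam, lam0, m, hyper_mean = 1.5, model = "DLI")
  manual <- log_species_prior(5) + sum(-lam0 / 1.5 - log(1.5))
  for (i in 1:3) {
    dv <- distance_vector(dists[[i]]$trees[[gi[i]]], S,
                          dists[[i]]$family$leaf_species, "DLI")
    manual <- manual + log(dists[[i]]$weights[gi[i]]) -
      sum(as.numeric(dv) / (m[[i]] * lam[i, ])) +
      sum(-lam[i, ] / lam0 - log(lam0))
  }
  expect_equal(lj, manual)
})

test_that("partition function matches direct enumeration and its limits", {
  species <- c("A", "B", "C")
  fam3 <- gene_family(1, c("A_1", "B_1", "C_1"), species)
  S <- ape::read.tree(text = "((A,B),C);")
  # 3-leaf family: a single unrooted topology
  z3 <- partition_function_bruteforce(fam3, S, rep(1, 3), rep(1, 3), model = "DLI")
  expect_equal(z3, 1)  # all distances 0 for the unique topology
  # 4-leaf family, lambda -> infinity: Z -> number of topologies (3)
  fam4 <- gene_family(1, c("A_1", "B_1", "C_1", "A_2"), species)
  z4 <- partition_function_bruteforce(fam4, S, rep(1e9, 3), rep(1, 3), model = "DLI")
  expect_equal(z4, 3, tolerance = 1e-6)
  # 5-leaf family at finite lambda: matches an independent 15-term sum
  fam5 <- gene_family(1, c("A_1", "B_1", "C_1", "A_2", "B_2"), species)
  lam <- c(0.7, 1.3, 0.9); m <- c(2, 4, 3)
  z5 <- partition_function_bruteforce(fam5, S, lam, m, model = "DLI")
  topos <- all_topologies(fam5$leaves)
  expect_length(topos, 15L)
  direct <- sum(sapply(topos, function(t) {
    dv <- distance_vector(t, S, fam5$leaf_species, "DLI")
    exp(-sum(as.numeric(dv) / (m * lam)))
  }))
  expect_equal(z5, direct)
  expect_error(partition_function_bruteforce(
    gene_family(1, paste0("A_", 1:9), species), S, lam, m, model = "DLI"),
    "exchange")
})

test_that("normalized distance distribution sums to one over topology space", {
  species <- c("A", "B", "C", "D")
  fam <- gene_family(1, c("A_1", "B_1", "C_1", "D_1"), species)
  S <- ape::read.tree(text = "((A,B),(C,D));")
  lam <- c(0.4, 0.8, 0.6, 1.1); m <- c(3, 4, 2, 3)
  z <- partition_function_bruteforce(fam, S, lam, m, model = "DLIR")
  p <- sapply(all_topologies(fam$leaves), function(t) {
    dv <- distance_vector(t, S, fam$leaf_species, "DLIR")
    exp(-sum(as.numeric(dv) / (m * lam))) / z
  })
  expect_equal(sum(p), 1)
  # small lambda concentrates on minimum-scaled-distance topologies
  z0 <- partition_function_bruteforce(fam, S, rep(1e-3, 4), m, model = "DLIR")
  p0 <- sapply(all_topologies(fam$leaves), function(t) {
    dv <- distance_vector(t, S, fam$leaf_species, "DLIR")
    exp(-sum(as.numeric(dv) / (m * 1e-3))) / z0
  })
  best <- which(p0 > 1e-6)
  dsum <- sapply(all_topologies(fam$leaves), function(t)
    sum(as.numeric(distance_vector(t, S, fam$leaf_species, "DLIR")) / m))
  expect_true(all(dsum[best] == min(dsum)))
})
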