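# Sampler machinery: proposals, multiple-try updates, annealing, summaries.

make_dists <- function(species, gts, weights = NULL) {
  lapply(seq_along(gts), function(i) {
    trees <- lapply(gts[[i]], function(s) ape::read.tree(text = s))
    fam <- gene_family(i, trees[[1]]$tip.label, species)
    gene_tree_distribution(fam, trees,
                           if (is.null(weights)) NULL else weights[[i]])
  })
}

test_that("species-tree proposals are valid and NNI/reroot behave as stated", {
  set.seed(3)
  species <- paste0("S", 1:6)
  S <- rand_stree(species)
  for (mv in c("nni", "spr", "reroot")) {
    for (i in 1:30) {
      pr <- propose_species_tree(S, move = mv)
      expect_true(ape::is.rooted(pr$tree) && ape::is.binary(pr$tree))
      expect_setequal(pr$tree$tip.label, species)
      if (mv == "reroot") expect_true(same_unrooted(pr$tree, S))
    }
  }
  # 3-species NNI: proposals stay within the 3 rooted resolutions
  S3 <- ape::read.tree(text = "((A,B),C);")
  seen <- character(0)
  for (i in 1:60)
    seen <- c(seen, recsup:::rooted_key(propose_species_tree(S3, "nni")$tree))
  expect_lte(length(unique(seen)), 2L)  # the two alternative resolutions
  expect_false(recsup:::rooted_key(S3) %in% seen)
})

test_that("repeated proposals reach all 15 rooted 4-taxon trees", {
  set.seed(5)
  keys <- character(0)
  cur <- rand_stree(LETTERS[1:4])
  for (i in 1:400) {
    cur <- propose_species_tree(cur)$tree
    keys <- c(keys, recsup:::rooted_key(cur))
  }
  expect_equal(length(unique(keys)), 15L)
})

test_that("identical seeds give identical chains, different seeds converge to the same consensus", {
  species <- LETTERS[1:5]
  dists <- make_dists(species, list("(((A,B),C),(D,E));", "(((A,B),C),(D,E));"))
  cfg <- sampler_config(iterations = 600, seed = 21)
  ch1 <- run_chain(dists, species, cfg)
  ch2 <- run_chain(dists, species, cfg)
  expect_identical(ch1$species_newick, ch2$species_newick)
  expect_identical(ch1$lambda, ch2$lambda)
  ch3 <- run_chain(dists, species, sampler_config(iterations = 2000, seed = 99))
  ch4 <- run_chain(dists, species, sampler_config(iterations = 2000, seed = 1234))
  s3 <- summarize_posterior(ch3); s4 <- summarize_posterior(ch4)
  expect_true(same_unrooted(s3$consensus_unrooted, s4$consensus_unrooted))
})

test_that("with infinite penalties the species posterior is uniform", {
  set.seed(8)
  species <- LETTERS[1:4]
  dists <- make_dists(species, list("((A,B),(C,D));"))
  cfg <- sampler_config(iterations = 24000, burn_in = 0.2, thin = 4, seed = 2,
                        update_lambda = FALSE, update_lambda0 = FALSE)
  ch <- run_chain(dists, species, cfg, model = "DLI", m = 1,
                  lambda_init = matrix(1e9, 1, 3), lambda0_init = rep(1, 3))
  keys <- vapply(ch$species_newick, function(s)
    recsup:::rooted_key(ape::read.tree(text = s)), "")
  freq <- table(keys) / length(keys)
  expect_equal(length(freq), 15L)
  se <- sqrt((1 / 15) * (14 / 15) / length(keys))
  # thinning leaves autocorrelation; allow a generous multiple of the iid se
  expect_true(all(abs(freq - 1 / 15) < 12 * se))
})

test_that("GMTM species sampling matches the exactly enumerated posterior", {
  set.seed(12)
  species <- LETTERS[1:4]
  dists <- make_dists(species,
    list(c("((A,B),(C,D));", "((A,C),(B,D));", "(((A,B),C),D);"),
         c("((A,D),(B,C));", "((A,B),(C,D));")),
    weights = list(c(0.5, 0.3, 0.2), c(0.6, 0.4)))
  lam <- 0.3
  Sall <- all_topologies(species, rooted = TRUE)
  keys <- vapply(Sall, recsup:::rooted_key, "")
  post <- vapply(Sall, function(S) {
    pr <- 1
    for (d in dists) {
      s <- 0
      for (t in seq_along(d$trees)) {
        dv <- distance_vector(d$trees[[t]], S, d$family$leaf_species, "DLIR")
        s <- s + d$weights[t] * exp(-sum(as.numeric(dv) / lam))
      }
      pr <- pr * s
    }
    pr
  }, 0)
  post <- post / sum(post)
  cfg <- sampler_config(iterations = 24000, burn_in = 0.2, thin = 3, seed = 42,
                        update_lambda = FALSE, update_lambda0 = FALSE)
  ch <- run_chain(dists, species, cfg, model = "DLIR", m = 1,
                  lambda_init = matrix(lam, 2, 4), lambda0_init = rep(1, 4))
  rk <- vapply(ch$species_newick, function(s)
    recsup:::rooted_key(ape::read.tree(text = s)), "")
  emp <- as.numeric(table(factor(rk, levels = keys)) / length(rk))
  se <- sqrt(pmax(post * (1 - post), 1e-6) / length(rk))
  expect_true(all(abs(emp - post) < pmax(3 * 4 * se, 0.02)))
})

test_that("gene-tree resampling reweights the input distribution by the distance model", {
  set.seed(14)
  species <- LETTERS[1:4]
  S <- ape::read.tree(text = "((A,B),(C,D));")
  topos <- c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));")
  dists <- make_dists(species, list(topos), weights = list(c(0.2, 0.5, 0.3)))
  lam <- 0.4
  # exact reweighting g * f / sum
  f <- vapply(seq_along(topos), function(t) {
    dv <- distance_vector(dists[[1]]$trees[[t]], S, dists[[1]]$family$leaf_species, "DLIR")
    exp(-sum(as.numeric(dv) / lam))
  }, 0)
  exact <- dists[[1]]$weights * f
  exact <- exact / sum(exact)
  cfg <- sampler_config(iterations = 16000, burn_in = 0.2, thin = 2, seed = 3,
                        update_species = FALSE, update_lambda = FALSE,
                        update_lambda0 = FALSE)
  ch <- run_chain(dists, species, cfg, model = "DLIR", m = 1, init_tree = S,
                  lambda_init = matrix(lam, 1, 4), lambda0_init = rep(1, 4))
  emp <- tabulate(ch$gene_index[, 1], 3) / nrow(ch$gene_index)
  se <- sqrt(pmax(exact * (1 - exact), 1e-6) / nrow(ch$gene_index))
  expect_true(all(abs(emp - exact) < pmax(3 * 3 * se, 0.02)))
  # congruent topology gains weight relative to its input share
  expect_gt(emp[1], dists[[1]]$weights[1])
  # point-mass input never moves
  dp <- make_dists(species, list("((A,C),(B,D));"))
  chp <- run_chain(dp, species, sampler_config(iterations = 200, seed = 5),
                   model = "DLIR")
  expect_true(all(chp$gene_index == 1L))
})

test_that("single-block updates move only their block and are reproducible", {
  set.seed(16)
  species <- LETTERS[1:5]
  dists <- make_dists(species, list(c("(((A,B),C),(D,E));", "(((A,C),B),(D,E));")),
                      weights = list(c(0.7, 0.3)))
  st <- chain_state(dists, species, model = "DLIR")
  set.seed(7)
  s1 <- gmtm_update(st, "lambda0")
  expect_equal(s1$species_parent, st$species_parent)
  expect_equal(s1$gene_index, st$gene_index)
  expect_equal(s1$lambda, st$lambda)
  set.seed(7)
  s1b <- gmtm_update(st, "lambda0")
  expect_identical(s1$lambda0, s1b$lambda0)
  set.seed(9)
  s2 <- resample_gene_tree(st, family_i = 1)
  expect_equal(s2$species_parent, st$species_parent)
  expect_equal(s2$lambda, st$lambda)
  set.seed(11)
  s3 <- exchange_update(st, sampler_config(exchange = TRUE, aux_len = 10))
  expect_equal(s3$gene_index, st$gene_index)
  expect_equal(s3$lambda, st$lambda)
})

test_that("exchange acceptance with an identity proposal is neutral in expectation", {
  # lambda* = lambda, S* = S makes the exchange ratio exactly 1; the chain
  # with exchange on must therefore keep point-mass congruent data in place
  species <- LETTERS[1:4]
  S <- ape::read.tree(text = "((A,B),(C,D));")
  dists <- make_dists(species, list("((A,B),(C,D));"))
  cfg <- sampler_config(iterations = 300, seed = 13, exchange = TRUE,
                        aux_len = 20, update_lambda = FALSE, update_lambda0 = FALSE)
  ch <- run_chain(dists, species, cfg, model = "DLI", m = 1, init_tree = S,
                  lambda_init = matrix(0.05, 1, 3), lambda0_init = rep(1, 3))
  accs <- vapply(ch$species_newick, function(s)
    split_accuracy(S, ape::read.tree(text = s)), 0)
  expect_gt(mean(accs == 1), 0.9)
})

test_that("annealing recovers congruent truth and reports its best state", {
  species <- LETTERS[1:4]
  truth <- ape::read.tree(text = "((A,B),(C,D));")
  dists <- make_dists(species, list("((A,B),(C,D));", "((A,B),(C,D));"))
  an <- anneal(dists, species, sampler_config(iterations = 800, anneal = TRUE,
                                              seed = 31), model = "DLIR",
               lambda_fixed = 1, m = 1)
  expect_true(same_unrooted(an$species_tree, truth))
  total <- sum(vapply(seq_along(dists), function(i) {
    dv <- distance_vector(dists[[i]]$trees[[an$gene_index[i]]], an$species_tree,
                          dists[[i]]$family$leaf_species, "DLIR")
    sum(as.numeric(dv))
  }, 0))
  expect_equal(total, 0)
  # best state has the top log posterior among everything recorded
  expect_gte(an$log_posterior, max(an$chain$log_posterior))
})

test_that("posterior summaries compute MAP, consensus and credible sets", {
  species <- LETTERS[1:4]
  t1 <- "((A,B),(C,D));"; t2 <- "((A,C),(B,D));"; t3 <- "((A,D),(B,C));"
  fake <- structure(list(
    species_newick = c(rep(t1, 60), rep(t2, 30), rep(t3, 10)),
    log_posterior = c(rep(-10, 60), rep(-12, 30), rep(-13, 10)),
    gene_index = matrix(1L, 100, 1),
    dists = make_dists(species, list(t1)),
    state = list(N = 1L)), class = "recsup_chain")
  sm <- summarize_posterior(fake)
  expect_true(same_unrooted(sm$map_tree, ape::read.tree(text = t1)))
  # smallest set with cumulative frequency >= 0.95: 0.6 + 0.3 < 0.95, so all 3
  expect_length(sm$credible_set, 3L)
  expect_gte(sm$credible_mass, 0.95)
  # at 0.9 + 0.1 the first topology alone cannot cover 0.95 either
  fake9 <- fake
  fake9$species_newick <- c(rep(t1, 90), rep(t2, 10))
  fake9$log_posterior <- rep(-1, 100)
  expect_length(summarize_posterior(fake9)$credible_set, 2L)
  # single-topology sample: MAP = consensus, credible set of size 1
  fake1 <- fake
  fake1$species_newick <- rep(t1, 50)
  fake1$log_posterior <- rep(-1, 50)
  fake1$gene_index <- matrix(1L, 50, 1)
  sm1 <- summarize_posterior(fake1)
  expect_length(sm1$credible_set, 1L)
  expect_true(same_unrooted(sm1$map_tree, sm1$consensus))
  # equal conflicting topologies: unrooted consensus is a star
  fake2 <- fake
  fake2$species_newick <- c(rep(t1, 50), rep(t2, 50))
  fake2$log_posterior <- rep(-1, 100)
  fake2$gene_index <- matrix(1L, 100, 1)
  sm2 <- summarize_posterior(fake2)
  expect_length(recsup:::tree_split_keys(sm2$consensus_unrooted), 0L)
})

test_that("empirical transition flows balance on an enumerable instance", {
  set.seed(19)
  species <- LETTERS[1:3]
  dists <- make_dists(species, list("((A,B),C);"))
  cfg <- sampler_config(iterations = 12000, burn_in = 0.1, thin = 1, seed = 23,
                        update_lambda = FALSE, update_lambda0 = FALSE)
  ch <- run_chain(dists, species, cfg, model = "DLI", m = 1,
                  lambda_init = matrix(0.8, 1, 3), lambda0_init = rep(1, 3))
  rk <- vapply(ch$species_newick, function(s)
    recsup:::rooted_key(ape::read.tree(text = s)), "")
  states <- sort(unique(rk))
  for (a in states) for (b in states) {
    if (a >= b) next
    ab <- sum(rk[-length(rk)] == a & rk[-1] == b)
    ba <- sum(rk[-length(rk)] == b & rk[-1] == a)
    expect_lt(abs(ab - ba) / sqrt(max(ab + ba, 1)), 4)
  }
})

test_that("trace files carry the sampled parameters in TSV form", {
  species <- LETTERS[1:4]
  dists <- make_dists(species, list("((A,B),(C,D));"))
  ch <- run_chain(dists, species, sampler_config(iterations = 300, seed = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace(ch, f)
  tr <- utils::read.delim(f)
  expect_true(all(c("iteration", "log_posterior", "lambda0_dups") %in% names(tr)))
  expect_equal(nrow(tr), length(ch$log_posterior))
  expect_equal(tr$log_posterior, ch$log_posterior)
})
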