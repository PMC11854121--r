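test_that("simulate_tree builds reproducible ultrametric Yule trees", {
  t4 <- simulate_tree(4, seed = 1)
  expect_equal(length(t4$tip.label), 4)
  expect_equal(t4$Nnode, 3)                       # bifurcating
  expect_true(ape::is.ultrametric(t4, tol = 1e-9))

  t1 <- simulate_tree(50, seed = 2)
  t2 <- simulate_tree(50, seed = 2)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1),
                         ape::write.tree(simulate_tree(50, seed = 3))))
  depths <- ape::node.depth.edgelength(t1)[seq_len(50)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_error(simulate_tree(3), "at least 4")
})

test_that("evolve_optima has Brownian covariance and sister-pair similarity", {
  tree <- simulate_tree(10, seed = 4)
  sigma <- 0.8
  set.seed(5)
  reps <- replicate(500, ape::rTraitCont(tree, model = "BM", sigma = sigma,
                                         root.value = 0))
  emp <- cov(t(reps))
  theo <- sigma^2 * ape::vcv(tree)[rownames(emp), colnames(emp)]
  expect_lt(max(abs(emp - theo)) / max(theo), 0.15)   # Monte-Carlo oracle

  big <- simulate_tree(100, seed = 6)
  opt <- evolve_optima(big, sigma_bm = 1, seed = 7)
  D <- ape::cophenetic.phylo(big)
  ut <- upper.tri(D)
  nd <- abs(outer(opt, opt, "-"))[ut]
  qd <- D[ut] <= quantile(D[ut], 0.1)
  expect_lt(mean(nd[qd]), mean(nd[!qd]))              # signal property
  expect_identical(evolve_optima(big, 1, seed = 7), opt)
})

test_that("simulate_metacommunity normalizes and orders evenness by sigma", {
  m0 <- simulate_metacommunity(50, 0, seed = 1)
  expect_equal(m0, rep(1 / 50, 50))
  m2 <- simulate_metacommunity(500, 2, seed = 2)
  expect_equal(sum(m2), 1, tolerance = 1e-12)
  gini <- function(p) {
    p <- sort(p); n <- length(p)
    2 * sum(seq_len(n) * p) / (n * sum(p)) - (n + 1) / n
  }
  g_small <- sapply(1:5, function(s) gini(simulate_metacommunity(300, 0.5, s)))
  g_large <- sapply(1:5, function(s) gini(simulate_metacommunity(300, 3, s)))
  expect_true(all(g_large > g_small))
})

test_that("simulate_neutral concentrates on the metacommunity as m, N grow", {
  meta <- simulate_metacommunity(100, 1.5, seed = 3)
  tight <- simulate_neutral(meta, N = 20000, m = 1, n_samples = 6, seed = 4)
  loose <- simulate_neutral(meta, N = 20000, m = 0.02, n_samples = 6, seed = 4)
  mad_of <- function(tab) {
    rel <- sweep(unclass(tab), 2, colSums(tab), "/")
    mean(abs(rel - meta))
  }
  expect_lt(mad_of(tight), mad_of(loose))
  expect_true(all(colSums(tight) == 20000))
  # marginal occupancy matches the prediction within Monte-Carlo error
  tab <- simulate_neutral(meta, N = 1000, m = 0.3, n_samples = 30, seed = 5)
  occ <- occupancy_abundance(tab)
  keep <- meta > 1e-4 & meta < 0.5
  pred <- predict_occurrence(meta[keep], 300, log(2) / 1000)
  expect_lt(mean(abs(occ$observed_freq[keep] - pred)), 0.08)
})

test_that("simulate_selected recovers the neutral limit and filters hard", {
  tree <- simulate_tree(80, seed = 6)
  meta <- simulate_metacommunity(80, 1, seed = 7)
  names(meta) <- tree$tip.label
  opt <- evolve_optima(tree, 1, seed = 8)
  wide <- simulate_selected(meta, opt, rep(0, 8), sigma_sel = 1e4,
                            N = 50000, seed = 9)
  rel <- rowMeans(sweep(unclass(wide), 2, colSums(wide), "/"))
  expect_lt(mean(abs(rel - meta)), 2e-3)              # neutral limit

  narrow <- simulate_selected(meta, opt, c(-2, 2), sigma_sel = 0.3,
                              N = 5000, seed = 10)
  pres1 <- unclass(narrow)[, 1] > 0; pres2 <- unclass(narrow)[, 2] > 0
  expect_lt(mean(opt[pres1 & !pres2]), mean(opt[pres2 & !pres1]))
  expect_error(simulate_selected(meta, opt, 1e6, sigma_sel = 0.1, seed = 1),
               "underflow")
})

test_that("simulate_metabolites plants monotone drivers and records truth", {
  env <- seq(-2, 2, length.out = 10)
  met <- simulate_metabolites(env, n_compounds = 30, n_informative = 4,
                              coupling = 1, noise_sd = 1e-6, seed = 11)
  truth <- attr(met, "informative")
  expect_equal(truth, sprintf("C%03d", 1:4))
  for (id in truth)
    expect_true(all(diff(unclass(met)[id, ]) > 0))    # noiseless monotone
  expect_true(all(unclass(met) > 0))
  cls <- compound_classes(met)
  expect_equal(sum(cls == "informative"), 4)
  expect_error(simulate_metabolites(env, 5, 9), "exceeds")
})

test_that("scenarios are bit-reproducible and carry coherent truth", {
  s1 <- make_scenario("variable", seed = 12)
  s2 <- make_scenario("variable", seed = 12)
  expect_identical(unclass(s1$communities), unclass(s2$communities))
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(unclass(s1$metabolites), unclass(s2$metabolites))
  expect_equal(s1$truth$regime, "variable_selection")
  expect_true(all(rownames(s1$communities) %in% s1$tree$tip.label))
  expect_true(all(colSums(s1$communities) == 1000))
  expect_setequal(s1$taxonomy$taxon_id, rownames(s1$communities))

  ks <- make_keystone_scenario(seed = 13)
  expect_equal(ks$truth$keystone_genus, "G_keystone")
  planted <- ks$taxonomy$taxon_id[ks$taxonomy$genus == "G_keystone"]
  expect_setequal(planted, ks$truth$keystone_taxa)
  # the planted clade is monophyletic on the tree
  expect_true(ape::is.monophyletic(ks$tree, planted))

  expect_error(make_keystone_scenario(seed = 1, clade_size = 201, strict = TRUE),
               "available sizes")
})

test_that("write_scenario emits a readable plain-text bundle", {
  dir <- withr::local_tempdir()
  sc <- make_scenario("neutral", seed = 14, n_taxa = 40, n_samples = 6,
                      n_compounds = 10)
  write_scenario(sc, dir)
  tab <- read_asv_table(file.path(dir, "table.tsv"))
  expect_equal(unclass(tab), unclass(sc$communities))
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, sc$tree$tip.label)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_identical(tax$genus, sc$taxonomy$genus)
  met <- read_metabolite_table(file.path(dir, "metabolites.tsv"))
  strip <- function(x) matrix(as.numeric(x), nrow(x), dimnames = dimnames(x))
  expect_equal(strip(met), strip(sc$metabolites), tolerance = 1e-6)
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$env, unname(sc$env))
})

test_that("homogeneous selection is detectable at its default pool size", {
  # the regime needs a regional pool much larger than per-sample richness;
  # at the default 1000 taxa the signal is strongly negative (see vignette)
  means <- sapply(1:3, function(sd) {
    sc <- make_scenario("homogeneous", seed = sd)
    bn <- suppressWarnings(beta_nti(sc$communities, sc$tree, n_null = 199,
                                    seed = sd, pool = "table"))
    mean(bn$beta_nti[upper.tri(bn$beta_nti)], na.rm = TRUE)
  })
  expect_lt(median(means), -2)
  expect_true(all(means < -1))
})
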