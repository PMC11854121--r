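test_that("beta_mntd reproduces hand-computed values on the balanced tree", {
  tree <- balanced_tree()
  f <- matrix(c(1, 0, 0, 0,
                0, 0, 0.5, 0.5,
                0.5, 0.5, 0, 0), nrow = 4,
              dimnames = list(c("A", "B", "C", "D"), c("j", "k", "l")))
  tab <- asv_table(f, mode = "relative")
  bm <- beta_mntd(tab, tree)
  expect_equal(bm["j", "k"], 4.0, tolerance = 1e-12)
  expect_equal(bm["j", "l"], 0.5, tolerance = 1e-12)
  expect_equal(diag(bm), c(j = 0, k = 0, l = 0))
})

test_that("beta_mntd equals the brute-force double loop on random fixtures", {
  for (sd in 1:3) {
    tree <- simulate_tree(12, seed = sd)
    tab <- random_table(12, 6, N = 300, seed = sd + 50)
    rownames(tab) <- tree$tip.label
    tab <- asv_table(unclass(tab), mode = "counts")
    rel <- to_relative(tab)
    D <- ape::cophenetic.phylo(tree)[rownames(rel), rownames(rel)]
    expect_equal(beta_mntd(rel, tree), bmntd_brute(unclass(rel), D),
                 tolerance = 1e-12)
  }
})

test_that("the distance-permutation null equals literal tip relabeling", {
  tree <- simulate_tree(15, seed = 4)
  tab <- random_table(15, 5, N = 400, seed = 5)
  rownames(tab) <- tree$tip.label
  rel <- to_relative(asv_table(unclass(tab)))
  D <- ape::cophenetic.phylo(tree)[rownames(rel), rownames(rel)]
  set.seed(6)
  perm <- sample.int(15)
  via_perm <- assemblyscope:::bmntd_pairs_cpp(D, unclass(rel), perm - 1L)
  # literal relabeling: taxon i takes the tip position of taxon perm[i]
  relabeled <- rownames(rel)[perm]
  D2 <- D[relabeled, relabeled]
  dimnames(D2) <- list(rownames(rel), rownames(rel))
  via_label <- bmntd_brute(unclass(rel), D2)
  dimnames(via_perm) <- dimnames(via_label)
  expect_equal(via_perm, via_label, tolerance = 1e-12)
})

test_that("beta_nti is reproducible, scale-invariant, and sign-bounded", {
  tree <- simulate_tree(40, seed = 7)
  meta <- simulate_metacommunity(40, 1.5, seed = 8)
  names(meta) <- tree$tip.label
  tab <- simulate_neutral(meta, N = 500, m = 0.3, n_samples = 6, seed = 9)

  b1 <- beta_nti(tab, tree, n_null = 99, seed = 10)
  b2 <- beta_nti(tab, tree, n_null = 99, seed = 10)
  expect_identical(b1$beta_nti, b2$beta_nti)

  scaled <- tree
  scaled$edge.length <- scaled$edge.length * 7.3
  b3 <- beta_nti(tab, scaled, n_null = 99, seed = 10)
  expect_equal(b1$beta_nti, b3$beta_nti, tolerance = 1e-9)
  expect_equal(b3$beta_mntd_obs, b1$beta_mntd_obs * 7.3, tolerance = 1e-9)

  # two identical samples: obs betaMNTD = 0 <= every null, so betaNTI <= 0
  m <- unclass(tab); m[, 2] <- m[, 1]; colnames(m)[2] <- "S02"
  b4 <- suppressWarnings(beta_nti(asv_table(m), tree, n_null = 99, seed = 11))
  expect_equal(b4$beta_mntd_obs["S01", "S02"], 0)
  expect_lte(b4$beta_nti["S01", "S02"], 0)

  expect_error(beta_nti(tab, tree, n_null = 50), "at least 99")
})

test_that("turnover TSV export round-trips through the long format", {
  tree <- simulate_tree(20, seed = 21)
  meta <- simulate_metacommunity(20, 1, seed = 22)
  names(meta) <- tree$tip.label
  tab <- simulate_neutral(meta, N = 300, m = 0.5, n_samples = 5, seed = 23)
  bn <- beta_nti(tab, tree, n_null = 99, seed = 24)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_turnover(bn, path)
  m <- assemblyscope:::read_long_matrix(path, "beta_nti")
  ids <- bn$ids
  expect_equal(m[ids, ids][upper.tri(bn$beta_nti)],
               bn$beta_nti[upper.tri(bn$beta_nti)], tolerance = 1e-9)
})

test_that("niche_values computes abundance-weighted habitat preferences", {
  m <- matrix(c(0.5, 0.5, 0.5, 0, 0, 0.5), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  tab <- asv_table(m, mode = "relative")
  v <- c(s1 = 2, s2 = 4)
  nv <- niche_values(tab, v)
  expect_equal(nv[["B"]], 2)            # point mass on s1
  expect_equal(nv[["A"]], 3)            # equal relative abundance, midpoint
  # weighted case: f = (0.75, 0.25), v = (0, 4) -> 1
  m2 <- matrix(c(0.75, 0.25, 0.25, 0.75), 2, byrow = TRUE,
               dimnames = list(c("X", "Y"), c("a", "b")))
  expect_equal(niche_values(asv_table(m2, mode = "relative"),
                            c(a = 0, b = 4))[["X"]], 1)
  # absent taxon -> NA
  m3 <- rbind(m, Z = c(0, 0))
  expect_true(is.na(niche_values(asv_table(m3, mode = "relative"), v)[["Z"]]))
})

test_that("phylogenetic-signal correlogram finds Brownian signal, not noise", {
  hits <- 0; n_rep <- 10
  for (sd in seq_len(n_rep)) {
    tree <- simulate_tree(60, seed = 400 + sd)
    niche <- evolve_optima(tree, sigma_bm = 1, seed = 500 + sd)
    cg <- phylo_signal_correlogram(tree, niche, n_classes = 4, n_perm = 199,
                                   seed = sd)
    if (!is.na(cg$r[1]) && cg$r[1] > 0 && cg$p[1] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)

  # permuted niche values: p roughly uniform in the shortest class
  set.seed(9)
  tree <- simulate_tree(60, seed = 600)
  niche <- evolve_optima(tree, sigma_bm = 1, seed = 601)
  p_null <- replicate(20, {
    shuffled <- setNames(sample(niche), names(niche))
    phylo_signal_correlogram(tree, shuffled, n_classes = 4, n_perm = 99)$p[1]
  })
  expect_gt(mean(p_null), 0.2)
  expect_lt(mean(p_null), 0.8)

  const <- setNames(rep(1, 60), tree$tip.label)
  cg0 <- phylo_signal_correlogram(tree, const, n_classes = 4, n_perm = 99)
  expect_true(all(is.na(cg0$r)))
})
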