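test_that("alpha diversity matches hand values", {
  u <- alpha_diversity(c(10, 10, 10, 10))
  expect_equal(u$richness, 4)
  expect_equal(u$shannon, log(4), tolerance = 1e-12)
  expect_equal(u$pielou, 1, tolerance = 1e-12)

  d <- alpha_diversity(c(8, 0, 0))
  expect_equal(d$richness, 1)
  expect_equal(d$shannon, 0)
  expect_true(is.na(d$pielou))

  h <- alpha_diversity(c(6, 2))
  expect_equal(h$shannon, -0.75 * log(0.75) - 0.25 * log(0.25),
               tolerance = 1e-12)
  expect_error(alpha_diversity(c(0, 0)), "all-zero")

  tab <- random_table(20, 5)
  adiv <- alpha_diversity_table(tab)
  expect_equal(adiv$richness, unname(colSums(tab > 0)))
})

test_that("bray_curtis matches the brute-force loop, vegan, and hand values", {
  x <- matrix(c(1, 1, 0, 0, 1, 1), 3, dimnames = list(NULL, c("a", "b")))
  expect_equal(bray_curtis(x)["a", "b"], 0.5)
  xid <- cbind(a = c(2, 3), b = c(2, 3))
  expect_equal(bray_curtis(xid)["a", "b"], 0)
  xdis <- cbind(a = c(2, 0), b = c(0, 3))
  expect_equal(bray_curtis(xdis)["a", "b"], 1)

  tab <- random_table(10, 6, seed = 42)
  d <- bray_curtis(tab)
  expect_equal(d, bc_brute(unclass(tab)), tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))
  if (requireNamespace("vegan", quietly = TRUE)) {
    dv <- as.matrix(vegan::vegdist(t(unclass(tab)), method = "bray"))
    expect_equal(unname(d), unname(dv), tolerance = 1e-12)
  }
})

test_that("mantel_test handles identity, affinity, and agrees with vegan", {
  tab <- random_table(10, 8, seed = 9)
  d1 <- bray_curtis(tab)
  mt <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_equal(mt$p, 1 / 100)

  mt2 <- mantel_test(d1, 3 * d1 + 0.2, n_perm = 99, seed = 1)
  expect_equal(mt2$r, 1, tolerance = 1e-12)

  set.seed(4)
  d2 <- as.matrix(dist(rnorm(8)))
  dimnames(d2) <- dimnames(d1)
  if (requireNamespace("vegan", quietly = TRUE)) {
    for (m in c("pearson", "spearman")) {
      ours <- mantel_test(d1, d2, n_perm = 99, method = m, seed = 2)
      ref <- vegan::mantel(as.dist(d1), as.dist(d2), method = m,
                           permutations = 0)
      expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
    }
  }
  expect_error(mantel_test(d1, matrix(1, 8, 8) - diag(8)), "zero variance")
  expect_error(mantel_test(d1[1:3, 1:3], d1[1:3, 1:3]), "at least 4")
})

test_that("mantel_test p-values are calibrated under the null", {
  # independent random distance matrices: p approximately uniform
  set.seed(77)
  n_rep <- 400
  pvals <- replicate(n_rep, {
    d1 <- as.matrix(dist(runif(9)))
    d2 <- as.matrix(dist(runif(9)))
    mantel_test(d1, d2, n_perm = 99)$p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.001)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
})

test_that("cooccurrence_network applies thresholds and ignores row order", {
  set.seed(12)
  base <- matrix(rnorm(8 * 10), nrow = 8)
  m <- rbind(t1 = base[1, ], t2 = base[1, ] * 2,        # rho = 1 pair
             t3 = base[2, ], t4 = base[3, ], t5 = base[4, ],
             t6 = base[5, ], t7 = base[6, ], t8 = base[7, ])
  m <- abs(m) + 1
  m <- round(m * 100)
  colnames(m) <- sprintf("S%02d", 1:10)
  tab <- asv_table(m)
  net <- cooccurrence_network(tab, top_n = 8)
  e <- net$edges
  expect_true(any(e$source == "t1" & e$target == "t2" & e$sign == "positive"))
  expect_true(all(abs(e$rho) > 0.8))
  expect_true(all(e$p < 0.05))
  expect_lte(net$n_nodes, 8)

  perm <- sample(nrow(m))
  net2 <- cooccurrence_network(asv_table(m[perm, , drop = FALSE]), top_n = 8)
  key <- function(n) sort(paste(pmin(n$edges$source, n$edges$target),
                                pmax(n$edges$source, n$edges$target)))
  expect_identical(key(net), key(net2))

  expect_warning(cooccurrence_network(tab, top_n = 99), "exceeds available")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  expect_equal(nrow(read.delim(path)), net$n_edges)
})
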