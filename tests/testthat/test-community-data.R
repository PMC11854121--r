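test_that("asv_table validates identifiers, signs and modes", {
  tab <- toy_counts()
  expect_equal(unname(colSums(tab)), c(8, 6))
  expect_identical(taxon_ids(tab), c("A", "B", "C"))
  expect_identical(table_mode(tab), "counts")

  m <- unclass(tab)
  rownames(m) <- c("A", "A", "C")
  expect_error(asv_table(m), "duplicate taxon")
  m <- unclass(tab); m[2, 1] <- -1
  expect_error(asv_table(m), "negative entry.*taxon 'B'.*sample 's1'")
  m <- unclass(tab); m[2, 1] <- 2.5
  expect_error(asv_table(m), "integral")
  expect_error(asv_table(unclass(tab), mode = "relative"), "column sums of 1")
})

test_that("TSV read/write round-trips and rejects bad cells", {
  tab <- random_table(15, 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(tab, path)
  back <- read_asv_table(path)
  expect_equal(unclass(back), unclass(tab))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#ASV_ID\ts1\ts2", "A\t5\t0", "B\t-1\t2"), bad)
  expect_error(read_asv_table(bad), "negative entry.*'B'.*'s1'")
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#ASV_ID\ts1\ts2", "A\t5\t0", "B\tx\t2"), bad2)
  expect_error(read_asv_table(bad2), "non-numeric")

  # samples-as-rows dialect
  tpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample = colnames(tab), t(unclass(tab)), check.names = FALSE)
  write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unclass(read_asv_table(tpath, transpose = TRUE)), unclass(tab))
})

test_that("BIOM round-trip preserves the matrix", {
  skip_if_not_installed("biomformat")
  tab <- random_table(10, 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".biom")
  write_asv_table(tab, path, format = "biom")
  back <- read_asv_table(path, format = "biom")
  strip <- function(x) matrix(as.numeric(x), nrow(x), dimnames = dimnames(x))
  expect_equal(strip(unclass(back)[rownames(tab), colnames(tab)]),
               strip(unclass(tab)))
})

test_that("to_relative normalizes columns and refuses double application", {
  tab <- toy_counts()
  rel <- to_relative(tab)
  expect_equal(rel[, "s1"], c(A = 0.625, B = 0.375, C = 0))
  expect_equal(unname(colSums(rel)), c(1, 1), tolerance = 1e-12)
  expect_identical(unclass(rel) == 0, unclass(tab) == 0)
  expect_error(to_relative(rel), "double normalization")

  zero <- matrix(c(1, 0, 0, 0), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(to_relative(asv_table(zero)), "all-zero sample.*s2")
})

test_that("subsample_to_min_depth equalizes depths without inventing taxa", {
  tab <- random_table(30, 5, N = 200, seed = 7)
  # unequal depths
  m <- unclass(tab); m[, 2] <- m[, 2] * 2; m[1, 3] <- m[1, 3] + 57
  tab <- asv_table(m)
  depth <- min(colSums(tab))
  sub <- subsample_to_min_depth(tab, seed = 11)
  expect_true(all(colSums(sub) == depth))
  expect_true(all(unclass(sub) <= unclass(tab)))          # support direction
  expect_identical(unclass(sub)[, colSums(tab) == depth],
                   unclass(tab)[, colSums(tab) == depth]) # already-minimal kept
  expect_identical(unclass(subsample_to_min_depth(tab, seed = 11)),
                   unclass(sub))                          # determinism
  zero <- matrix(c(1, 0), 1, 2, dimnames = list("A", c("s1", "s2")))
  expect_error(subsample_to_min_depth(asv_table(zero), seed = 1), "depth is 0")
})

test_that("align_to_tree intersects and preserves order consistency", {
  tab <- toy_counts()
  tree <- ape::read.tree(text = "((B:1,C:1):1,D:2);")
  al <- align_to_tree(tab, tree)
  expect_setequal(rownames(al$table), c("B", "C"))
  expect_identical(rownames(al$table), al$tree$tip.label)

  tree_same <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  al2 <- align_to_tree(tab, tree_same)
  expect_setequal(al2$tree$tip.label, c("A", "B", "C"))
  expect_equal(sum(al2$table), sum(tab))

  disjoint <- ape::read.tree(text = "(X:1,Y:1);")
  expect_error(align_to_tree(tab, disjoint), "no taxa shared")
})

test_that("taxonomy parsing and rank aggregation conserve reads", {
  lin <- c(A = "k__Bacteria; p__P1; c__C1; o__O1; f__F1; g__Gx; s__",
           B = "k__Bacteria; p__P1; c__C1; o__O1; f__F1; g__Gx; s__sp",
           C = "k__Bacteria; p__P2")
  tax <- parse_taxonomy(lin)
  expect_identical(tax$genus, c("Gx", "Gx", NA))
  expect_identical(tax$phylum, c("P1", "P1", "P2"))

  tab <- toy_counts()
  agg <- aggregate_by_rank(tab, tax, "genus")
  expect_equal(agg["Gx", ], c(s1 = 8, s2 = 2))         # A + B
  expect_equal(agg["Unassigned", ], c(s1 = 0, s2 = 4)) # C pooled
  expect_equal(colSums(agg), colSums(tab))             # conservation
  expect_error(aggregate_by_rank(tab, tax, "cohort"), "unknown rank")

  # all unassigned -> single row of column sums
  tax_none <- parse_taxonomy(c(A = "", B = "", C = ""))
  agg2 <- aggregate_by_rank(tab, tax_none, "genus")
  expect_identical(rownames(agg2), "Unassigned")
  expect_equal(unname(agg2[1, ]), unname(colSums(tab)))
})

test_that("metabolite table validates and round-trips", {
  m <- matrix(runif(12), 3, 4,
              dimnames = list(c("RET40", "RET44", "RET46"), sprintf("S%02d", 1:4)))
  met <- metabolite_table(m, class = c(RET40 = "Phytol", RET44 = "Phytol",
                                       RET46 = "other"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metabolite_table(met, path)
  back <- read_metabolite_table(path)
  expect_equal(unclass(back), unclass(met), tolerance = 1e-12)
  expect_identical(unname(compound_classes(back)), c("Phytol", "Phytol", "other"))

  m[1, 1] <- -2
  expect_error(metabolite_table(m), "non-negative")
})
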