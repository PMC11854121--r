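# Small builders shared across test files.  Everything is generated in code;
# no fixture files.

toy_counts <- function() {
  # rows: A = (5,0), B = (3,2), C = (0,4); column sums (8, 6)
  m <- matrix(c(5, 0, 3, 2, 0, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  asv_table(m, mode = "counts")
}

# the hand-computable 4-taxon balanced tree
balanced_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

random_table <- function(n_taxa, n_samples, N = 500, seed = 1) {
  set.seed(seed)
  meta <- exp(rnorm(n_taxa))
  counts <- sapply(seq_len(n_samples), function(s)
    rmultinom(1, N, meta / sum(meta))[, 1])
  dimnames(counts) <- list(sprintf("T%04d", seq_len(n_taxa)),
                           sprintf("S%02d", seq_len(n_samples)))
  asv_table(counts, mode = "counts")
}

# Reference betaMNTD: literal double loop over samples and taxa.
bmntd_brute <- function(rel, D) {
  ns <- ncol(rel)
  out <- matrix(0, ns, ns, dimnames = list(colnames(rel), colnames(rel)))
  for (a in seq_len(ns)) for (b in seq_len(ns)) {
    if (a == b) next
    pa <- which(rel[, a] > 0); pb <- which(rel[, b] > 0)
    s1 <- sum(sapply(pa, function(i) rel[i, a] * min(D[i, pb])))
    s2 <- sum(sapply(pb, function(i) rel[i, b] * min(D[i, pa])))
    out[a, b] <- 0.5 * (s1 + s2)
  }
  out
}

# Reference Bray-Curtis: literal formula, double loop.
bc_brute <- function(x) {
  ns <- ncol(x)
  out <- matrix(0, ns, ns, dimnames = list(colnames(x), colnames(x)))
  for (a in seq_len(ns)) for (b in seq_len(ns)) {
    if (a == b) next
    out[a, b] <- 1 - 2 * sum(pmin(x[, a], x[, b])) / sum(x[, a] + x[, b])
  }
  out
}
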