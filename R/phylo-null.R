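#' Abundance-weighted beta mean nearest taxon distance
#'
#' For every pair of samples, the abundance-weighted mean of the patristic
#' distance from each taxon present in one sample to its nearest relative
#' present in the other (a taxon shared by both samples contributes 0),
#' averaged over both directions:
#' \deqn{\beta MNTD(a,b) = \tfrac12\Big[\sum_i f_{ia}\min_{j: f_{jb}>0} d(i,j)
#'   + \sum_i f_{ib}\min_{j: f_{ja}>0} d(i,j)\Big]}
#' with f the within-sample relative abundance and d the cophenetic
#' (patristic) distance on the tree.
#'
#' @param table an [asv_table()] whose taxa all appear on `tree` (use
#'   [align_to_tree()] first).  Counts are converted to relative abundances
#'   internally.
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param weighted if `FALSE`, every present taxon gets weight 1/richness
#'   instead of its relative abundance.
#' @return Symmetric samples-x-samples matrix of betaMNTD values.
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  prep <- bmntd_prepare(table, tree, weighted, pool = "table")
  out <- bmntd_pairs_cpp(prep$D, prep$F, seq_len(nrow(prep$F)) - 1L)
  dimnames(out) <- list(colnames(table), colnames(table))
  out
}

# Shared validation/conversion for beta_mntd / beta_nti.
bmntd_prepare <- function(table, tree, weighted = TRUE,
                          pool = c("occupied", "table")) {
  pool <- match.arg(pool)
  stopifnot(inherits(table, "asv_table"), inherits(tree, "phylo"))
  if (!setequal(rownames(table), tree$tip.label))
    stop("table taxa and tree tips differ; run align_to_tree() first")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  rel <- if (is_counts(table)) to_relative(table) else table
  F <- unclass(rel)
  if (!weighted) {
    pres <- F > 0
    F <- sweep(pres * 1, 2, colSums(pres), "/")
  }
  # pool = "occupied": the tip-shuffle pool is the set of taxa observed in
  # at least one sample; all-zero rows are dropped so they neither receive
  # labels in the null nor perturb the RNG stream (removing an unobserved
  # taxon is then an exact no-op).  pool = "table" keeps every row: use it
  # when the table's rows encode a known regional pool wider than the
  # observed taxa (e.g. simulation ground truth) — required to detect
  # homogeneous selection when every sample experienced the same filter.
  if (pool == "occupied") {
    occupied <- rowSums(F) > 0
    if (!all(occupied)) {
      F <- F[occupied, , drop = FALSE]
      tree <- ape::keep.tip(tree, rownames(F))
    }
  }
  D <- ape::cophenetic.phylo(tree)
  D <- D[rownames(F), rownames(F)]
  if (any(colSums(F > 0) == 0))
    stop("sample(s) with no taxa present: ",
         paste(colnames(F)[colSums(F > 0) == 0], collapse = ", "))
  list(D = D, F = F)
}

#' beta nearest taxon index (betaNTI)
#'
#' Standardizes observed betaMNTD against a null distribution obtained by
#' shuffling taxon labels across all tips of the tree (equivalently,
#' permuting the rows/columns of the patristic distance matrix while the
#' abundance matrix stays fixed):
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \mu_{null}) / \sigma_{null}}
#' |betaNTI| > 2 for a sample pair indicates that selection (a deterministic
#' process) dominates its phylogenetic turnover; the sign separates variable
#' (> 2) from homogeneous (< -2) selection.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip-shuffle randomizations (>= 99).
#' @param seed integer seed for the null permutations.
#' @param pool taxa eligible for the tip shuffle: `"occupied"` (default)
#'   restricts the regional pool to taxa observed in at least one sample —
#'   the only pool available for real tables, and the choice that makes
#'   removing a never-observed taxon an exact no-op; `"table"` shuffles
#'   across every row of the table, so all-zero rows act as known regional
#'   pool members (needed to detect homogeneous selection in simulations
#'   where every sample is identically filtered).
#' @return An object of class `turnover_matrices`: list with `ids`,
#'   `beta_mntd_obs`, `null_mean`, `null_sd`, `beta_nti` (diagonal `NA`),
#'   `n_null`, `seed`.
#' @export
beta_nti <- function(table, tree, n_null = 999, seed = NULL, weighted = TRUE,
                     pool = c("occupied", "table")) {
  if (n_null < 99) stop("n_null must be at least 99")
  prep <- bmntd_prepare(table, tree, weighted, pool = pool)
  nt <- nrow(prep$F)
  ids <- colnames(table)
  obs <- bmntd_pairs_cpp(prep$D, prep$F, seq_len(nt) - 1L)
  perms <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) sample.int(nt) - 1L, integer(nt))
  })
  nul <- bmntd_null_cpp(prep$D, prep$F, perms)
  bnti <- (obs - nul$mean) / nul$sd
  # degenerate nulls: all shuffles give the same betaMNTD.  When the
  # observed value equals it too (e.g. two samples with identical taxon
  # membership: every contribution is 0 under observed and null alike)
  # there is no deviation and betaNTI = 0; a genuine discrepancy with a
  # zero-sd null cannot be standardized and stays NA.
  zero_sd <- nul$sd == 0
  if (any(zero_sd & upper.tri(nul$sd))) {
    agree <- abs(obs - nul$mean) < 1e-12
    bnti[zero_sd & agree] <- 0
    if (any(zero_sd & !agree & upper.tri(nul$sd))) {
      warning(sum(zero_sd & !agree & upper.tri(nul$sd)),
              " sample pair(s) with null sd = 0 and nonzero deviation; betaNTI NA")
      bnti[zero_sd & !agree] <- NA_real_
    }
  }
  diag(bnti) <- NA_real_
  dimnames(obs) <- dimnames(nul$mean) <- dimnames(nul$sd) <-
    dimnames(bnti) <- list(ids, ids)
  structure(list(ids = ids, beta_mntd_obs = obs, null_mean = nul$mean,
                 null_sd = nul$sd, beta_nti = bnti, n_null = n_null,
                 seed = seed),
            class = "turnover_matrices")
}

#' @export
print.turnover_matrices <- function(x, ...) {
  v <- upper_vec(x$beta_nti)
  cat(sprintf("turnover_matrices: %d samples, %d nulls; mean betaNTI = %.3f (sd %.3f)\n",
              length(x$ids), x$n_null, mean(v, na.rm = TRUE),
              stats::sd(v, na.rm = TRUE)))
  invisible(x)
}

#' Write betaNTI results as long-format TSV
#'
#' Columns: sample_a, sample_b, beta_mntd, null_mean, null_sd, beta_nti.
#'
#' @param x a [beta_nti()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_turnover <- function(x, path) {
  stopifnot(inherits(x, "turnover_matrices"))
  idx <- which(upper.tri(x$beta_nti), arr.ind = TRUE)
  df <- data.frame(sample_a = x$ids[idx[, 1]], sample_b = x$ids[idx[, 2]],
                   beta_mntd = x$beta_mntd_obs[idx],
                   null_mean = x$null_mean[idx], null_sd = x$null_sd[idx],
                   beta_nti = x$beta_nti[idx],
                   stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Abundance-weighted niche value per taxon
#'
#' The habitat preference of a taxon for an environmental variable:
#' niche_i = sum_s f_is v_s / sum_s f_is, the abundance-weighted mean of the
#' variable over the samples the taxon occurs in.
#'
#' @param table an [asv_table()].
#' @param variable numeric vector, one finite value per sample (in table
#'   column order, or named by sample id).
#' @return Named numeric vector, one value per taxon; `NA` for taxa absent
#'   everywhere.
#' @export
niche_values <- function(table, variable) {
  stopifnot(inherits(table, "asv_table"))
  if (!is.null(names(variable))) variable <- variable[colnames(table)]
  if (length(variable) != ncol(table) || !all(is.finite(variable)))
    stop("`variable` must provide one finite value per sample")
  rel <- if (is_counts(table)) to_relative(table) else table
  F <- unclass(rel)
  tot <- rowSums(F)
  out <- as.vector(F %*% variable) / tot
  out[tot == 0] <- NA_real_
  stats::setNames(out, rownames(table))
}

#' Phylogenetic-signal Mantel correlogram
#'
#' Tests whether closely related taxa have similar niche values: taxon pairs
#' are binned into `n_classes` equal-count phylogenetic-distance classes and,
#' within each class, the correlation between phylogenetic distance and
#' absolute niche difference is assessed by permuting niche values across
#' taxa.  A positive, significant correlation in the shortest-distance
#' class is the phylogenetic signal that justifies betaNTI.
#'
#' @param tree a rooted [ape::phylo].
#' @param niche named per-taxon niche values (see [niche_values()]); taxa
#'   with `NA` are dropped.
#' @param n_classes number of distance classes.
#' @param n_perm permutations per class.
#' @param seed integer seed.
#' @return data.frame with one row per class: `class`, `d_min`, `d_max`,
#'   `n_pairs`, `r`, `p` (`NA` when a class has zero variance).
#' @export
phylo_signal_correlogram <- function(tree, niche, n_classes = 5,
                                     n_perm = 999, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  niche <- niche[!is.na(niche)]
  taxa <- intersect(tree$tip.label, names(niche))
  if (length(taxa) < 20) stop("need >= 20 taxa with niche values")
  D <- ape::cophenetic.phylo(tree)[taxa, taxa]
  v <- niche[taxa]
  nt <- length(taxa)
  ut <- upper.tri(D)
  pd <- D[ut]
  breaks <- stats::quantile(pd, probs = seq(0, 1, length.out = n_classes + 1))
  # ultrametric trees tie many patristic distances; collapse duplicate breaks
  breaks <- unique(breaks)
  if (length(breaks) < 3)
    stop("phylogenetic distances too degenerate to form distance classes")
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  n_classes <- length(breaks) - 1
  cls <- cut(pd, breaks = breaks, labels = FALSE)
  nd_obs <- abs(outer(v, v, "-"))[ut]
  r_obs <- rep(NA_real_, n_classes)
  for (k in seq_len(n_classes)) {
    m <- cls == k
    if (stats::var(pd[m]) > 0 && stats::var(nd_obs[m]) > 0)
      r_obs[k] <- stats::cor(pd[m], nd_obs[m])
  }
  hits <- integer(n_classes)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      vp <- v[sample.int(nt)]
      ndp <- abs(outer(vp, vp, "-"))[ut]
      for (k in seq_len(n_classes)) {
        if (is.na(r_obs[k])) next
        m <- cls == k
        if (stats::var(ndp[m]) > 0 && stats::cor(pd[m], ndp[m]) >= r_obs[k])
          hits[k] <- hits[k] + 1L
      }
    }
  })
  data.frame(class = seq_len(n_classes),
             d_min = tapply(pd, cls, min)[as.character(seq_len(n_classes))],
             d_max = tapply(pd, cls, max)[as.character(seq_len(n_classes))],
             n_pairs = as.integer(table(factor(cls, levels = seq_len(n_classes)))),
             r = r_obs,
             p = ifelse(is.na(r_obs), NA_real_, (1 + hits) / (1 + n_perm)),
             stringsAsFactors = FALSE, row.names = NULL)
}
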