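#' Five-way ecological process classification of a sample pair
#'
#' Applies the standard betaNTI / RCbray decision rule: betaNTI > 2 means
#' variable selection, betaNTI < -2 homogeneous selection; otherwise
#' (|betaNTI| < 2, no dominant selection) RC > 0.95 means dispersal
#' limitation, RC < -0.95 homogenizing dispersal, and anything else drift.
#' All inequalities are strict, so boundary values fall through to the
#' weaker category.
#'
#' @param bnti betaNTI z-score(s).
#' @param rc_scaled RCbray value(s) in [-1, 1] (standard sign convention).
#' @return Character vector over
#'   \{variable_selection, homogeneous_selection, dispersal_limitation,
#'   homogenizing_dispersal, drift\}; `NA` where either input is missing.
#' @examples
#' classify_pair(2.5, 0.1)    # variable_selection
#' classify_pair(0.5, -0.97)  # homogenizing_dispersal
#' @export
classify_pair <- function(bnti, rc_scaled) {
  n <- max(length(bnti), length(rc_scaled))
  bnti <- rep_len(bnti, n); rc_scaled <- rep_len(rc_scaled, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(bnti) & !is.na(rc_scaled)
  out[ok & bnti > 2] <- "variable_selection"
  out[ok & bnti < -2] <- "homogeneous_selection"
  rest <- ok & is.na(out)
  out[rest & rc_scaled > 0.95] <- "dispersal_limitation"
  out[rest & rc_scaled < -0.95] <- "homogenizing_dispersal"
  out[ok & is.na(out)] <- "drift"
  out
}

process_levels <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal", "drift")

#' Process fractions per sample group
#'
#' Classifies every sample pair in scope with [classify_pair()] and tallies
#' the five process labels per group, along with the deterministic fraction
#' (both selection labels), stochastic fraction (the other three) and mean
#' betaNTI.
#'
#' @param bnti_matrix symmetric betaNTI matrix (e.g. `$beta_nti` from
#'   [beta_nti()]).
#' @param rc_matrix symmetric RCbray matrix (`$rc_scaled` from [rc_bray()]),
#'   same ids.
#' @param groups per-sample group labels (named by sample id, or in matrix
#'   order); `NULL` puts all samples in one group.
#' @param scope `"within_group"` tallies only pairs whose samples share a
#'   group; `"between_group"` tallies only pairs from different groups,
#'   under a single `"between"` group; `"all_pairs"` tallies every pair
#'   under a single `"all"` group.
#' @return data.frame, one row per group: pair count, count and fraction of
#'   each label, deterministic/stochastic fractions, mean betaNTI.
#' @export
partition_fractions <- function(bnti_matrix, rc_matrix, groups = NULL,
                                scope = c("within_group", "between_group",
                                          "all_pairs")) {
  scope <- match.arg(scope)
  bnti_matrix <- as.matrix(bnti_matrix); rc_matrix <- as.matrix(rc_matrix)
  if (!identical(dim(bnti_matrix), dim(rc_matrix)))
    stop("betaNTI and RC matrices have different dimensions")
  ids <- rownames(bnti_matrix)
  n <- nrow(bnti_matrix)
  if (is.null(groups)) groups <- rep("all", n)
  if (!is.null(names(groups)) && !is.null(ids)) groups <- groups[ids]
  if (length(groups) != n) stop("`groups` must give one label per sample")
  groups_eff <- if (scope == "all_pairs") rep("all", n) else groups
  idx <- which(upper.tri(bnti_matrix), arr.ind = TRUE)
  ga <- groups_eff[idx[, 1]]; gb <- groups_eff[idx[, 2]]
  if (scope == "between_group") {
    keep <- ga != gb
    grp <- rep("between", sum(keep))
  } else {
    keep <- ga == gb
    grp <- ga[keep]
    small <- setdiff(unique(groups_eff), unique(grp))
    if (length(small) > 0)
      warning("group(s) with < 2 samples skipped: ",
              paste(small, collapse = ", "))
  }
  lab <- classify_pair(bnti_matrix[idx][keep], rc_matrix[idx][keep])
  bn <- bnti_matrix[idx][keep]
  rows <- lapply(unique(grp), function(g) {
    sel <- grp == g & !is.na(lab)
    cnt <- table(factor(lab[sel], levels = process_levels))
    tot <- sum(cnt)
    frac <- if (tot > 0) as.numeric(cnt) / tot else rep(NA_real_, 5)
    det <- sum(frac[1:2]); sto <- sum(frac[3:5])
    data.frame(group = g, n_pairs = tot,
               t(stats::setNames(as.numeric(cnt), paste0("n_", process_levels))),
               t(stats::setNames(frac, paste0("frac_", process_levels))),
               deterministic = det, stochastic = sto,
               mean_bnti = mean(bn[grp == g], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean betaNTI within / between sample groups
#'
#' @param bnti_matrix symmetric betaNTI matrix.
#' @param groups per-sample group labels (named or in matrix order).
#' @return data.frame with one row per group pair (including within-group
#'   pairs) and the mean betaNTI over its sample pairs.
#' @export
mean_bnti_by_group <- function(bnti_matrix, groups) {
  bnti_matrix <- as.matrix(bnti_matrix)
  ids <- rownames(bnti_matrix)
  if (!is.null(names(groups)) && !is.null(ids)) groups <- groups[ids]
  idx <- which(upper.tri(bnti_matrix), arr.ind = TRUE)
  key <- apply(cbind(groups[idx[, 1]], groups[idx[, 2]]), 1,
               function(r) paste(sort(r), collapse = " vs "))
  v <- bnti_matrix[idx]
  agg <- tapply(v, key, mean, na.rm = TRUE)
  data.frame(groups = names(agg), mean_bnti = as.numeric(agg),
             n_pairs = as.integer(table(key)[names(agg)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Leave-one-genus-out keystone screen
#'
#' Screens genera for a keystone role in community assembly:
#' \enumerate{
#'   \item aggregate the table to genus level and keep genera whose mean
#'     within-sample relative abundance exceeds `min_rel_abund`;
#'   \item for each retained genus, Mantel-test the pairwise
#'     |delta genus relative abundance| matrix against the full-community
#'     betaNTI matrix;
#'   \item remove each genus in turn (all its ASVs; tree pruned; remaining
#'     abundances renormalized per sample), recompute betaNTI with the same
#'     seed protocol, and record the post-removal mean betaNTI;
#'   \item flag a genus as a `flip` when the full-community mean betaNTI
#'     exceeds +2 but drops below +2 once the genus is removed — i.e. the
#'     genus carries the variable-selection signal.
#' }
#'
#' @param table a counts-mode [asv_table()] aligned (or alignable) to `tree`.
#' @param tree rooted [ape::phylo] covering the table's taxa.
#' @param taxonomy taxonomy data.frame (see [parse_taxonomy()]) with a
#'   `genus` column.
#' @param min_rel_abund genus mean relative-abundance filter (default 1%).
#' @param n_null betaNTI randomizations per run.
#' @param seed integer seed, reused for every leave-one-out run so
#'   differences reflect the removal, not null noise.
#' @param n_perm Mantel permutations.
#' @param compute_rc also recompute RCbray after each removal (slower);
#'   adds a `mean_rc_removed` column.
#' @param weighted abundance-weighted betaMNTD (see [beta_mntd()]).
#' @return Object of class `keystone_screen`: list with `full_mean_bnti`,
#'   `n_null`, `seed`, and `genera`, a data.frame per retained genus:
#'   mean_rel_abund, mantel_r, mantel_p, mean_bnti_removed, flip.
#' @export
keystone_loo_screen <- function(table, tree, taxonomy, min_rel_abund = 0.01,
                                n_null = 999, seed = NULL, n_perm = 999,
                                compute_rc = FALSE, weighted = TRUE) {
  stopifnot(inherits(table, "asv_table"))
  al <- align_to_tree(table, tree)
  table <- al$table; tree <- al$tree
  lab <- taxonomy$genus[match(rownames(table), taxonomy$taxon_id)]
  lab[is.na(lab)] <- "Unassigned"
  rel <- to_relative(table)
  genus_rel <- rowsum(unclass(rel), lab)
  mean_ra <- rowMeans(genus_rel)
  keep <- setdiff(names(mean_ra)[mean_ra > min_rel_abund], "Unassigned")
  full <- beta_nti(table, tree, n_null = n_null, seed = seed,
                   weighted = weighted)
  full_mean <- mean(upper_vec(full$beta_nti), na.rm = TRUE)
  rows <- lapply(keep, function(g) {
    gvec <- genus_rel[g, ]
    gd <- abs(outer(gvec, gvec, "-"))
    mt <- tryCatch(mantel_test(gd, zero_diag(full$beta_nti),
                               n_perm = n_perm, seed = seed),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    drop_taxa <- rownames(table)[lab == g]
    sub <- unclass(table)[setdiff(rownames(table), drop_taxa), , drop = FALSE]
    cs <- colSums(sub)
    if (any(cs == 0)) {
      warning("genus '", g, "' removal empties sample(s) ",
              paste(colnames(sub)[cs == 0], collapse = ", "), "; dropped")
      sub <- sub[, cs > 0, drop = FALSE]
    }
    # remaining abundances renormalized per sample (betaMNTD weights must be
    # a proper distribution)
    sub_tab <- to_relative(asv_table(sub, mode = "counts"))
    sub_tree <- ape::keep.tip(tree, rownames(sub))
    bn <- beta_nti(sub_tab, sub_tree, n_null = n_null, seed = seed,
                   weighted = weighted)
    mean_rm <- mean(upper_vec(bn$beta_nti), na.rm = TRUE)
    rc_rm <- NA_real_
    if (compute_rc) {
      rc <- rc_bray(asv_table(sub, mode = "counts"), n_null = n_null,
                    seed = seed)
      rc_rm <- mean(upper_vec(rc$rc_scaled), na.rm = TRUE)
    }
    data.frame(genus = g, mean_rel_abund = mean_ra[g],
               mantel_r = mt$r, mantel_p = mt$p,
               mean_bnti_removed = mean_rm, mean_rc_removed = rc_rm,
               flip = full_mean > 2 && mean_rm < 2,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  genera <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(genus = character(), mean_rel_abund = numeric(),
               mantel_r = numeric(), mantel_p = numeric(),
               mean_bnti_removed = numeric(), mean_rc_removed = numeric(),
               flip = logical(), stringsAsFactors = FALSE)
  structure(list(full_mean_bnti = full_mean, n_null = n_null, seed = seed,
                 min_rel_abund = min_rel_abund, genera = genera),
            class = "keystone_screen")
}

# Mantel machinery rejects NA diagonals; betaNTI matrices carry NA there.
zero_diag <- function(m) { diag(m) <- 0; m }

#' @export
print.keystone_screen <- function(x, ...) {
  cat(sprintf("keystone_screen: full-community mean betaNTI = %.3f; %d genera screened, %d flip(s)\n",
              x$full_mean_bnti, nrow(x$genera), sum(x$genera$flip)))
  if (any(x$genera$flip))
    cat("  flips:", paste(x$genera$genus[x$genera$flip], collapse = ", "), "\n")
  invisible(x)
}
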