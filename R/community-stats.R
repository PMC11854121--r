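#' Alpha diversity of one sample
#'
#' @param column non-negative abundance vector for a single sample (counts or
#'   relative abundances), total > 0.
#' @return A list with `richness` (number of taxa present), `shannon`
#'   (H = -sum q log q in nats, over present taxa, q the within-sample
#'   relative abundance) and `pielou` (H / log(richness); `NA` when only one
#'   taxon is present).
#' @examples
#' alpha_diversity(c(10, 10, 10, 10))  # H = log(4), evenness 1
#' @export
alpha_diversity <- function(column) {
  if (any(column < 0) || anyNA(column)) stop("abundances must be non-negative")
  tot <- sum(column)
  if (tot == 0) stop("all-zero sample")
  q <- column[column > 0] / tot
  s <- length(q)
  h <- -sum(q * log(q))
  list(richness = s, shannon = h,
       pielou = if (s > 1) h / log(s) else NA_real_)
}

#' Per-sample alpha diversity table
#'
#' @param table an [asv_table()].
#' @return data.frame with one row per sample: richness, shannon, pielou.
#' @export
alpha_diversity_table <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  res <- lapply(seq_len(ncol(table)), function(j) alpha_diversity(table[, j]))
  data.frame(sample_id = colnames(table),
             richness = vapply(res, `[[`, numeric(1), "richness"),
             shannon = vapply(res, `[[`, numeric(1), "shannon"),
             pielou = vapply(res, `[[`, numeric(1), "pielou"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(j,k) = 1 - 2 sum_i min(x_ij, x_ik) / sum_i (x_ij + x_ik), computed on
#' the table's values as given (apply [to_relative()] first for
#' composition-based dissimilarity).
#'
#' @param table an [asv_table()] or plain taxa-x-samples matrix.
#' @return Symmetric samples-x-samples matrix with zero diagonal, in [0,1].
#' @export
bray_curtis <- function(table) {
  x <- unclass(table)
  tot <- colSums(x)
  if (any(tot == 0))
    stop("empty sample(s): ", paste(colnames(x)[tot == 0], collapse = ", "))
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (j in seq_len(n - 1)) {
    xj <- x[, j]
    for (k in (j + 1):n) {
      s <- sum(pmin(xj, x[, k]))
      d[j, k] <- d[k, j] <- 1 - 2 * s / (tot[j] + tot[k])
    }
  }
  d
}

#' Mantel permutation test
#'
#' Correlates the upper triangles of two distance matrices and assesses
#' significance by permuting the ids of the second matrix.  The p-value is
#' one-tailed (greater) with the +1 correction:
#' p = (1 + #\{r* >= r\}) / (1 + n_perm).
#'
#' @param d1,d2 symmetric distance matrices over the same ids, in the same
#'   order.
#' @param n_perm number of permutations.
#' @param method `"pearson"` or `"spearman"`.
#' @param seed integer seed (NULL = use current RNG state).
#' @return list(r =, p =, n_perm =).
#' @export
mantel_test <- function(d1, d2, n_perm = 999, method = c("pearson", "spearman"),
                        seed = NULL) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dim(d1), dim(d2)))
    stop("distance matrices have different dimensions")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("distance matrices must share ids in the same order")
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 ids for a Mantel test")
  ut <- upper.tri(d1)
  if (stats::var(d1[ut]) == 0 || stats::var(d2[ut]) == 0)
    stop("zero variance in a distance-matrix triangle")
  if (method == "spearman") {
    # the upper-triangle multiset is invariant under simultaneous row/column
    # permutation, so ranks can be assigned once and then permuted with the
    # matrix instead of re-ranking every permutation
    d1[ut] <- rank(d1[ut]); d1[lower.tri(d1)] <- t(d1)[lower.tri(d1)]
    d2[ut] <- rank(d2[ut]); d2[lower.tri(d2)] <- t(d2)[lower.tri(d2)]
  }
  v1 <- d1[ut]
  v1c <- v1 - mean(v1)
  denom1 <- sqrt(sum(v1c^2))
  corfun <- function(m2) {
    v2 <- m2[ut]
    v2c <- v2 - mean(v2)
    sum(v1c * v2c) / (denom1 * sqrt(sum(v2c^2)))
  }
  r_obs <- corfun(d2)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      if (corfun(d2[p, p]) >= r_obs) hits <- hits + 1L
    }
  })
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}

#' Spearman co-occurrence network
#'
#' Ranks taxa by mean relative abundance, keeps the `top_n` most abundant,
#' and draws an edge between two taxa when the Spearman correlation of their
#' abundance profiles satisfies |rho| > `rho_threshold` with p < `alpha`
#' (t-approximation, no multiplicity correction).
#'
#' @param table an [asv_table()] with >= 4 samples.
#' @param top_n number of most-abundant taxa to retain.
#' @param rho_threshold absolute-correlation threshold for an edge.
#' @param alpha significance level for the correlation p-value.
#' @return An object of class `cooccurrence_network`: list with `nodes`
#'   (taxon ids), `edges` (data.frame source, target, rho, p, sign) and
#'   summary counts.
#' @export
cooccurrence_network <- function(table, top_n = 150, rho_threshold = 0.8,
                                 alpha = 0.05) {
  stopifnot(inherits(table, "asv_table"))
  if (ncol(table) < 4) stop("need at least 4 samples")
  rel <- if (is_counts(table)) to_relative(table) else table
  keep_n <- min(top_n, nrow(table))
  if (top_n > nrow(table))
    warning("top_n exceeds available taxa; using all ", nrow(table))
  ord <- order(rowMeans(unclass(rel)), decreasing = TRUE)[seq_len(keep_n)]
  ord <- sort(ord)  # edge set must not depend on row order
  sub <- unclass(rel)[ord, , drop = FALSE]
  ids <- rownames(sub)
  rho <- stats::cor(t(sub), method = "spearman")
  n <- ncol(sub)
  # t-approximation for the Spearman correlation p-value (two-sided)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  pval[abs(rho) >= 1] <- 0
  keep <- which(upper.tri(rho) & abs(rho) > rho_threshold & pval < alpha,
                arr.ind = TRUE)
  edges <- data.frame(source = ids[keep[, 1]], target = ids[keep[, 2]],
                      rho = rho[keep], p = pval[keep],
                      sign = ifelse(rho[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = ids, edges = edges,
                 n_nodes = length(ids), n_edges = nrow(edges),
                 n_positive = sum(edges$sign == "positive"),
                 n_negative = sum(edges$sign == "negative"),
                 rho_threshold = rho_threshold, alpha = alpha),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (%d +, %d -), |rho| > %g, p < %g\n",
              x$n_nodes, x$n_edges, x$n_positive, x$n_negative,
              x$rho_threshold, x$alpha))
  invisible(x)
}

#' Export a co-occurrence network
#'
#' @param network a [cooccurrence_network()].
#' @param path output path.
#' @param format `"tsv"` (edge list) or `"graphml"` (requires igraph).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("GraphML export requires the 'igraph' package")
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
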