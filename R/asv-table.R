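#' Construct an ASV table
#'
#' An `asv_table` holds a taxa-by-samples abundance matrix together with a
#' mode flag distinguishing raw read counts from relative abundances.  The
#' mode is explicit rather than inferred from the values so that accidental
#' double normalization is a detectable error.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns, with
#'   unique non-empty dimnames.  In `"counts"` mode entries must be
#'   non-negative integers; in `"relative"` mode every column must sum to 1
#'   (within 1e-9).
#' @param mode `"counts"` or `"relative"`.
#' @return An object of class `asv_table`: the matrix with a `mode`
#'   attribute and accessors [taxon_ids()], [sample_ids()].
#' @examples
#' m <- matrix(c(5, 3, 0, 0, 2, 4), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' tab <- asv_table(m)
#' colSums(tab)
#' @export
asv_table <- function(counts, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("`counts` contains missing values")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative entry at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  if (mode == "counts") {
    if (any(abs(counts - round(counts)) > 1e-9))
      stop("counts mode requires integral entries")
    storage.mode(counts) <- "double"
    counts <- round(counts)
  } else {
    cs <- colSums(counts)
    off <- which(abs(cs - 1) > 1e-9)
    if (length(off) > 0)
      stop("relative mode requires column sums of 1; offending samples: ",
           paste(colnames(counts)[off], collapse = ", "))
  }
  structure(counts, mode = mode, class = c("asv_table", "matrix", "array"))
}

#' @rdname asv_table
#' @param x an `asv_table`.
#' @export
taxon_ids <- function(x) rownames(x)

#' @rdname asv_table
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname asv_table
#' @export
table_mode <- function(x) attr(x, "mode")

is_counts <- function(x) identical(attr(x, "mode"), "counts")

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d taxa x %d samples (%s mode)\n",
              nrow(x), ncol(x), attr(x, "mode")))
  utils::str(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Read an ASV table from TSV or BIOM
#'
#' TSV layout follows the classic QIIME convention: first column holds taxon
#' ids, header row holds sample ids, cells hold read counts.  Use
#' `transpose = TRUE` for samples-as-rows files.  BIOM files are read through
#' the biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param transpose for TSV only: set `TRUE` when rows are samples.
#' @return A counts-mode [asv_table()] with file order preserved.
#' @export
read_asv_table <- function(path, format = c("tsv", "biom"), transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(asv_table(m, mode = "counts"))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
                 arr.ind = TRUE)
    r <- bad[1, 1]; c <- bad[1, 2]
    stop(sprintf("non-numeric entry '%s' at taxon '%s', sample '%s'",
                 m[r, c], ids[r], colnames(m)[c]))
  }
  rownames(m) <- ids
  if (transpose) m <- t(m)
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative entry at taxon '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  asv_table(m, mode = "counts")
}

#' Write an ASV table to TSV or BIOM
#'
#' @param table an [asv_table()].
#' @param path output file path.
#' @param format `"tsv"` or `"biom"`.
#' @param id_column header for the taxon-id column in TSV output.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path, format = c("tsv", "biom"),
                            id_column = "#ASV_ID") {
  format <- match.arg(format)
  stopifnot(inherits(table, "asv_table"))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("writing BIOM requires the 'biomformat' package")
    b <- biomformat::make_biom(unclass(table))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- data.frame(id = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its read total.  Refuses already-relative
#' input so the normalization cannot be applied twice.
#'
#' @param table a counts-mode [asv_table()].
#' @return A relative-mode `asv_table`; zero pattern preserved.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  if (!is_counts(table))
    stop("table is already in relative mode (double normalization)")
  tot <- colSums(table)
  if (any(tot == 0))
    stop("all-zero sample(s): ", paste(colnames(table)[tot == 0], collapse = ", "))
  asv_table(sweep(unclass(table), 2, tot, "/"), mode = "relative")
}

#' Rarefy every sample to the minimum observed depth
#'
#' Subsamples each column without replacement (multivariate hypergeometric)
#' down to the smallest sample total, the usual rarefaction used before
#' alpha-diversity comparison.
#'
#' @param table a counts-mode [asv_table()].
#' @param seed integer seed; the operation is reproducible given the seed.
#' @return A counts-mode `asv_table` in which every column sums to the
#'   minimum input depth.  Samples already at that depth are left untouched.
#' @export
subsample_to_min_depth <- function(table, seed) {
  stopifnot(inherits(table, "asv_table"))
  if (!is_counts(table)) stop("rarefaction requires counts mode")
  tot <- colSums(table)
  depth <- min(tot)
  if (depth == 0)
    stop("minimum sample depth is 0 (sample ",
         colnames(table)[which.min(tot)], ")")
  out <- unclass(table)
  with_seed(seed, {
    for (j in seq_len(ncol(out))) {
      if (tot[j] == depth) next
      out[, j] <- rhyper_vector(out[, j], depth)
    }
  })
  asv_table(out, mode = "counts")
}

# Multivariate hypergeometric draw: subsample `k` individuals without
# replacement from urn counts `x`, via sequential univariate hypergeometrics.
rhyper_vector <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  remaining <- sum(x)
  for (i in seq_len(n)) {
    if (k == 0) break
    xi <- x[i]
    draw <- stats::rhyper(1, xi, remaining - xi, k)
    out[i] <- draw
    k <- k - draw
    remaining <- remaining - xi
  }
  out
}

#' Restrict an ASV table and a phylogeny to their shared taxa
#'
#' @param table an [asv_table()].
#' @param tree an [ape::phylo] tree whose tip labels are taxon ids.
#' @return `list(table=, tree=)` with the table rows ordered as the pruned
#'   tree's tip labels.
#' @export
align_to_tree <- function(table, tree) {
  stopifnot(inherits(table, "asv_table"), inherits(tree, "phylo"))
  shared <- intersect(rownames(table), tree$tip.label)
  if (length(shared) == 0)
    stop("no taxa shared between table and tree")
  drop <- setdiff(tree$tip.label, shared)
  if (length(drop) > 0) tree <- ape::drop.tip(tree, drop)
  tab <- unclass(table)[tree$tip.label, , drop = FALSE]
  mode <- attr(table, "mode")
  if (mode == "relative" && any(abs(colSums(tab) - 1) > 1e-9)) {
    # dropping off-tree taxa breaks the unit column sums; renormalize
    cs <- colSums(tab)
    if (any(cs == 0))
      stop("sample(s) left empty after pruning to tree: ",
           paste(colnames(tab)[cs == 0], collapse = ", "))
    tab <- sweep(tab, 2, cs, "/")
    warning("relative abundances renormalized after dropping off-tree taxa")
  }
  list(table = asv_table(tab, mode = mode), tree = tree)
}
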