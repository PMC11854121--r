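#' Read and parse a QIIME-style taxonomy table
#'
#' Expects a TSV with taxon ids in the first column and a lineage string in
#' the second (e.g. `k__Bacteria; p__Proteobacteria; ...; g__Rhizobium`).
#' Lineages are split on `";"`, rank prefixes (`k__`, `p__`, ...) are
#' stripped, and empty or unparsable ranks become `NA`.
#'
#' @param path TSV file path.
#' @param ranks rank names assigned to the lineage positions.
#' @return A `data.frame` with one row per taxon: `taxon_id` plus one column
#'   per rank; missing ranks are `NA`.
#' @export
read_taxonomy <- function(path,
                          ranks = c("kingdom", "phylum", "class", "order",
                                    "family", "genus", "species")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  parse_taxonomy(stats::setNames(as.character(df[[2]]), as.character(df[[1]])),
                 ranks = ranks)
}

#' @rdname read_taxonomy
#' @param lineages named character vector, taxon id -> lineage string.
#' @export
parse_taxonomy <- function(lineages,
                           ranks = c("kingdom", "phylum", "class", "order",
                                     "family", "genus", "species")) {
  if (anyDuplicated(names(lineages)))
    stop("duplicate taxon ids in taxonomy")
  parts <- strsplit(lineages, ";", fixed = TRUE)
  m <- matrix(NA_character_, nrow = length(lineages), ncol = length(ranks),
              dimnames = list(NULL, ranks))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[a-zA-Z]__", "", p)
    p[p == "" | is.na(p)] <- NA_character_
    n <- min(length(p), length(ranks))
    m[i, seq_len(n)] <- p[seq_len(n)]
  }
  data.frame(taxon_id = names(lineages), m,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate an ASV table to a taxonomic rank
#'
#' Sums rows of the table over all ASVs sharing the same value at `rank`.
#' ASVs missing from the taxonomy or with `NA` at the rank are pooled into a
#' single `"Unassigned"` row, so per-sample totals are conserved exactly.
#'
#' @param table an [asv_table()].
#' @param taxonomy data.frame from [read_taxonomy()]/[parse_taxonomy()].
#' @param rank a rank column name of `taxonomy` (e.g. `"genus"`).
#' @return An `asv_table` (same mode) whose rows are the distinct rank
#'   values plus, if needed, `"Unassigned"`.
#' @export
aggregate_by_rank <- function(table, taxonomy, rank = "genus") {
  stopifnot(inherits(table, "asv_table"))
  if (!rank %in% names(taxonomy))
    stop("unknown rank '", rank, "'; available: ",
         paste(setdiff(names(taxonomy), "taxon_id"), collapse = ", "))
  lab <- taxonomy[[rank]][match(rownames(table), taxonomy$taxon_id)]
  lab[is.na(lab)] <- "Unassigned"
  groups <- unique(lab)
  out <- matrix(0, nrow = length(groups), ncol = ncol(table),
                dimnames = list(groups, colnames(table)))
  for (g in groups)
    out[g, ] <- colSums(unclass(table)[lab == g, , drop = FALSE])
  asv_table(out, mode = attr(table, "mode"))
}
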