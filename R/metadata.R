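#' Read sample metadata
#'
#' TSV with sample ids in the first column; remaining columns are numeric
#' measurements (soil chemistry, enzyme activities, root or growth traits)
#' or categorical group labels (treatment, habitat).
#'
#' @param path TSV file path.
#' @return A `data.frame` with rownames = sample ids.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in metadata")
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  num <- vapply(df, is.numeric, logical(1))
  bad <- names(df)[num][!vapply(df[num], function(v) all(is.finite(v)), logical(1))]
  if (length(bad) > 0)
    stop("non-finite values in metadata column(s): ", paste(bad, collapse = ", "))
  df
}

#' Construct a metabolite intensity table
#'
#' @param intensities non-negative numeric matrix, compounds x samples, with
#'   unique compound rownames and sample colnames.
#' @param name optional named character vector of compound display names.
#' @param class optional named character vector assigning each compound to a
#'   compound class/group (used for class-level driver screening).
#' @return An object of class `metabolite_table` (matrix with `name` and
#'   `class` attributes).
#' @export
metabolite_table <- function(intensities, name = NULL, class = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix (compounds x samples)")
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("`intensities` must have compound rownames and sample colnames")
  if (anyDuplicated(rownames(intensities))) stop("duplicate compound ids")
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  ids <- rownames(intensities)
  cls <- if (is.null(class)) stats::setNames(rep(NA_character_, length(ids)), ids)
         else stats::setNames(as.character(class[ids]), ids)
  nm <- if (is.null(name)) stats::setNames(ids, ids)
        else stats::setNames(as.character(name[ids]), ids)
  structure(intensities, name = nm, compound_class = cls,
            class = c("metabolite_table", "matrix", "array"))
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table: %d compounds x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read a metabolite table from TSV
#'
#' Layout: first column compound id; optional `name` and `class` columns;
#' remaining columns are per-sample intensities.
#'
#' @param path TSV file path.
#' @return A [metabolite_table()].
#' @export
read_metabolite_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  nm <- cls <- NULL
  if ("name" %in% names(df)) {
    nm <- stats::setNames(as.character(df$name), ids); df$name <- NULL
  }
  if ("class" %in% names(df)) {
    cls <- stats::setNames(as.character(df$class), ids); df$class <- NULL
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  metabolite_table(m, name = nm, class = cls)
}

#' Write a metabolite table to TSV
#'
#' @param metabolites a [metabolite_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(metabolites, path) {
  stopifnot(inherits(metabolites, "metabolite_table"))
  df <- data.frame(compound_id = rownames(metabolites),
                   name = attr(metabolites, "name"),
                   class = attr(metabolites, "compound_class"),
                   unclass(metabolites), check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname metabolite_table
#' @param x a `metabolite_table`.
#' @export
compound_classes <- function(x) attr(x, "compound_class")
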