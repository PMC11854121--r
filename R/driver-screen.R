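#' Coefficient-of-variation prefilter for metabolites
#'
#' CV = sample standard deviation / mean of each compound's intensities
#' across samples.  Compounds varying little across samples (CV below the
#' threshold) cannot track a turnover signal and are screened out before the
#' distance-matrix correlation.
#'
#' @param metabolites a [metabolite_table()].
#' @param cv_threshold compounds pass when CV > this value.
#' @return data.frame per compound: `compound_id`, `cv`, `passed`.  A
#'   zero-mean compound gets `cv = NA` and does not pass.
#' @export
cv_filter <- function(metabolites, cv_threshold = 0.5) {
  stopifnot(inherits(metabolites, "metabolite_table"))
  m <- unclass(metabolites)
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  data.frame(compound_id = rownames(m), cv = cv,
             passed = !is.na(cv) & cv > cv_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise distance matrix from per-sample variables
#'
#' A single variable gives |v_j - v_k|; a multi-column block gives the
#' Euclidean distance on z-scored columns (so each member variable
#' contributes on a common scale, and per-column affine rescaling does not
#' change the result).
#'
#' @param values numeric vector (one value per sample) or a samples-x-
#'   variables matrix/data.frame.
#' @return Symmetric samples-x-samples distance matrix.
#' @export
variable_distance <- function(values) {
  if (is.null(dim(values))) {
    if (!all(is.finite(values))) stop("values must be finite")
    if (stats::var(values) == 0) stop("constant variable (zero variance)")
    d <- abs(outer(values, values, "-"))
    dimnames(d) <- list(names(values), names(values))
    return(d)
  }
  m <- as.matrix(values)
  if (!all(is.finite(m))) stop("values must be finite")
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0)) stop("all variables constant (zero variance)")
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- scale(m)
  d <- as.matrix(stats::dist(z))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Screen metabolites for drivers of betaNTI
#'
#' For each compound passing the CV prefilter (and, optionally, for each
#' compound class as a z-scored block), runs a Mantel test between the
#' pairwise |delta intensity| matrix and the betaNTI matrix.  A compound is
#' selected as a putative regulator of community assembly when its Mantel
#' r exceeds `r_threshold` and (unless `use_alpha = FALSE`) its permutation
#' p-value is below `alpha` after Benjamini-Hochberg adjustment across the
#' screened compounds.  BH adjustment is the default because a raw
#' per-compound alpha of 0.05 selects about 5% of pure-noise compounds
#' (roughly 5 false positives per 100 compounds screened); under BH the
#' probability of selecting anything from pure noise is about alpha.  Set
#' `p_adjust = "none"` for the raw per-compound rule.
#'
#' @param bnti_matrix symmetric betaNTI matrix (`$beta_nti` from
#'   [beta_nti()]); diagonal may be `NA`.
#' @param metabolites a [metabolite_table()] whose samples match the betaNTI
#'   ids.
#' @param cv_threshold CV prefilter threshold ([cv_filter()]).
#' @param r_threshold Mantel-r selection threshold.
#' @param alpha permutation p-value threshold; set `use_alpha = FALSE` to
#'   reproduce a pure r-based rule.
#' @param use_alpha apply the p < alpha condition in addition to r.
#' @param p_adjust `"BH"` (default) or `"none"`; with BH the smallest
#'   achievable adjusted p is bounded below by the permutation count, so
#'   keep `n_perm` >= 999 when screening ~100 compounds.
#' @param n_perm Mantel permutations.
#' @param method correlation type for the Mantel test; `"spearman"`
#'   (default) is invariant to monotone transforms of the intensities,
#'   which matters because metabolite intensities are typically lognormal.
#' @param seed integer seed.
#' @param classes optionally screen compound classes too: uses the table's
#'   class labels ([compound_classes()]); class distance is Euclidean on the
#'   z-scored member compounds.
#' @return Object of class `driver_screen`: list with `compounds` (per
#'   compound: cv, passed_cv, mantel_r, p, selected; sorted by r) and
#'   `classes` (per class: n_compounds, mantel_r, p), or `NULL` when class
#'   screening is off.
#' @export
bnti_driver_screen <- function(bnti_matrix, metabolites, cv_threshold = 0.5,
                               r_threshold = 0.2, alpha = 0.05,
                               use_alpha = TRUE, n_perm = 999,
                               method = c("spearman", "pearson"),
                               p_adjust = c("BH", "none"),
                               seed = NULL, classes = FALSE) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(metabolites, "metabolite_table"))
  bnti_matrix <- as.matrix(bnti_matrix)
  ids <- rownames(bnti_matrix)
  if (is.null(ids)) stop("betaNTI matrix must carry sample ids")
  if (!all(ids %in% colnames(metabolites)))
    stop("metabolite table is missing sample(s): ",
         paste(setdiff(ids, colnames(metabolites)), collapse = ", "))
  if (length(ids) < 6) stop("need at least 6 samples")
  m <- unclass(metabolites)[, ids, drop = FALSE]
  bn <- zero_diag(bnti_matrix)
  cvt <- cv_filter(metabolites, cv_threshold)
  res <- data.frame(compound_id = cvt$compound_id, cv = cvt$cv,
                    passed_cv = cvt$passed, mantel_r = NA_real_,
                    p = NA_real_, selected = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in which(res$passed_cv)) {
    v <- m[res$compound_id[i], ]
    if (stats::var(v) == 0) next
    mt <- mantel_test(variable_distance(v), bn, n_perm = n_perm,
                      method = method, seed = seed)
    res$mantel_r[i] <- mt$r
    res$p[i] <- mt$p
  }
  res$p_adj <- NA_real_
  tested <- !is.na(res$p)
  res$p_adj[tested] <- if (p_adjust == "BH")
    stats::p.adjust(res$p[tested], method = "BH") else res$p[tested]
  res$selected <- res$passed_cv & !is.na(res$mantel_r) &
    res$mantel_r > r_threshold &
    (!use_alpha | (!is.na(res$p_adj) & res$p_adj < alpha))
  res <- res[order(-ifelse(is.na(res$mantel_r), -Inf, res$mantel_r)), ]
  rownames(res) <- NULL
  cls_res <- NULL
  if (isTRUE(classes)) {
    cls <- compound_classes(metabolites)
    levs <- unique(cls[!is.na(cls)])
    rows <- lapply(levs, function(cl) {
      members <- rownames(m)[!is.na(cls) & cls == cl]
      block <- t(m[members, , drop = FALSE])
      d <- tryCatch(variable_distance(block), error = function(e) NULL)
      if (is.null(d)) {
        warning("class '", cl, "' skipped (no usable member compounds)")
        return(NULL)
      }
      mt <- mantel_test(d, bn, n_perm = n_perm, method = method, seed = seed)
      data.frame(class = cl, n_compounds = length(members),
                 mantel_r = mt$r, p = mt$p,
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    cls_res <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  }
  structure(list(compounds = res, classes = cls_res,
                 cv_threshold = cv_threshold, r_threshold = r_threshold,
                 alpha = if (use_alpha) alpha else NA_real_,
                 n_perm = n_perm, seed = seed),
            class = "driver_screen")
}

#' @export
print.driver_screen <- function(x, ...) {
  cat(sprintf("driver_screen: %d compounds, %d passed CV > %g, %d selected (r > %g%s)\n",
              nrow(x$compounds), sum(x$compounds$passed_cv),
              sum(x$compounds$selected), x$r_threshold,
              if (!is.na(x$alpha)) sprintf(", p < %g", x$alpha) else ""))
  invisible(x)
}
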