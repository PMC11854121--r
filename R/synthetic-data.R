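#' Simulate an ultrametric phylogeny
#'
#' Pure-birth (Yule) tree with unit birth rate, tips labeled `T0001`,
#' `T0002`, ... in tree order.
#'
#' @param n_tips number of tips (>= 4).
#' @param seed integer seed.
#' @return A rooted ultrametric [ape::phylo].
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 4) stop("need at least 4 tips")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$tip.label <- sprintf("T%04d", seq_len(n_tips))
  tree
}

#' Evolve niche optima by Brownian motion
#'
#' Simulates a continuous trait down the tree from a root value of 0 with
#' increment variance `sigma_bm^2` per unit branch length, so tip values are
#' jointly normal with covariance `sigma_bm^2` times the shared root-to-tip
#' path length.  Close relatives therefore have similar optima — the
#' phylogenetic signal in habitat preference that betaNTI requires.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param sigma_bm trait standard deviation per unit branch length (> 0).
#' @param seed integer seed.
#' @return Named numeric vector of tip optima.
#' @export
evolve_optima <- function(tree, sigma_bm = 1, seed = NULL) {
  if (sigma_bm <= 0) stop("sigma_bm must be positive")
  with_seed(seed,
            ape::rTraitCont(tree, model = "BM", sigma = sigma_bm,
                            root.value = 0))
}

#' Simulate lognormal metacommunity abundances
#'
#' @param n_taxa number of taxa (>= 2).
#' @param lognormal_sigma sd of log abundance; 0 gives the uniform
#'   metacommunity 1/n_taxa.
#' @param seed integer seed.
#' @return Numeric vector of relative abundances summing to 1.
#' @export
simulate_metacommunity <- function(n_taxa, lognormal_sigma = 2, seed = NULL) {
  if (n_taxa < 2) stop("need at least 2 taxa")
  x <- with_seed(seed, exp(stats::rnorm(n_taxa, 0, lognormal_sigma)))
  x / sum(x)
}

#' Simulate neutrally assembled local communities
#'
#' Samples each community from the stationary distribution of the neutral
#' model: per taxon, a latent local frequency from
#' Beta(N m p_i, N m (1 - p_i)), the latent vector renormalized, and counts
#' drawn as multinomial(N).  This matches the beta marginals that
#' [fit_neutral_model()] assumes, making parameter recovery a clean
#' round-trip test.
#'
#' @param meta metacommunity relative abundances (summing to 1); names, if
#'   present, become taxon ids, else `T0001`, ...
#' @param N reads per sample (>= 100).
#' @param m migration probability in (0, 1].
#' @param n_samples number of independent local communities.
#' @param seed integer seed.
#' @return A counts-mode [asv_table()] with samples `S01`, `S02`, ...
#' @export
simulate_neutral <- function(meta, N = 1000, m = 0.3, n_samples = 12,
                             seed = NULL) {
  if (N < 100) stop("N must be at least 100")
  if (m <= 0 || m > 1) stop("m must lie in (0, 1]")
  nt <- length(meta)
  ids <- if (!is.null(names(meta))) names(meta) else sprintf("T%04d", seq_len(nt))
  Nm <- N * m
  counts <- with_seed(seed, {
    vapply(seq_len(n_samples), function(s) {
      lat <- stats::rbeta(nt, Nm * meta, Nm * (1 - meta))
      lat[!is.finite(lat)] <- 0
      if (sum(lat) == 0) lat <- meta
      stats::rmultinom(1, N, lat / sum(lat))[, 1]
    }, numeric(nt))
  })
  dimnames(counts) <- list(ids, sprintf("S%02d", seq_len(n_samples)))
  asv_table(counts, mode = "counts")
}

#' Simulate communities under Gaussian environmental filtering
#'
#' Per sample s, taxon weights are
#' w_i(s) = meta_i * exp(-(optima_i - env_s)^2 / (2 sigma_sel^2)) and counts
#' are multinomial(N, w(s)).  Small `sigma_sel` is strong selection; as
#' sigma_sel grows the weights revert to the neutral metacommunity.
#'
#' @param meta metacommunity relative abundances.
#' @param optima per-taxon niche optima (same length/order as `meta`).
#' @param env per-sample environment values, one per community.
#' @param sigma_sel niche breadth (> 0), trait units.
#' @param N reads per sample.
#' @param seed integer seed.
#' @return A counts-mode [asv_table()].
#' @export
simulate_selected <- function(meta, optima, env, sigma_sel = 0.5, N = 1000,
                              seed = NULL) {
  if (sigma_sel <= 0) stop("sigma_sel must be positive")
  if (length(optima) != length(meta)) stop("meta and optima lengths differ")
  nt <- length(meta)
  ids <- if (!is.null(names(meta))) names(meta)
         else if (!is.null(names(optima))) names(optima)
         else sprintf("T%04d", seq_len(nt))
  counts <- with_seed(seed, {
    vapply(seq_along(env), function(s) {
      w <- meta * exp(-(optima - env[s])^2 / (2 * sigma_sel^2))
      if (sum(w) <= 0)
        stop("all selection weights underflowed to 0 at env = ", env[s],
             "; increase sigma_sel")
      stats::rmultinom(1, N, w / sum(w))[, 1]
    }, numeric(nt))
  })
  dimnames(counts) <- list(ids, sprintf("S%02d", seq_along(env)))
  asv_table(counts, mode = "counts")
}

#' Simulate a metabolite matrix with planted drivers
#'
#' Informative compounds have log intensity `coupling * env + noise`; the
#' remaining compounds are pure lognormal noise.  All intensities are
#' positive.
#'
#' @param env per-sample environment values.
#' @param n_compounds total compounds.
#' @param n_informative how many compounds track `env` (first
#'   `n_informative` ids).
#' @param coupling slope of log intensity on env for informative compounds.
#' @param noise_sd sd of the log-scale noise.
#' @param seed integer seed.
#' @param sample_ids optional sample ids (default `S01`, ...).
#' @return A [metabolite_table()]; the planted compound ids are in
#'   `attr(, "informative")` and their class label is `"informative"`
#'   (others `"noise"`).
#' @export
simulate_metabolites <- function(env, n_compounds = 100, n_informative = 5,
                                 coupling = 1, noise_sd = 0.3, seed = NULL,
                                 sample_ids = NULL) {
  if (n_informative > n_compounds) stop("n_informative exceeds n_compounds")
  ns <- length(env)
  ids <- sprintf("C%03d", seq_len(n_compounds))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(ns))
  m <- with_seed(seed, {
    out <- matrix(0, n_compounds, ns)
    for (i in seq_len(n_compounds)) {
      base <- stats::rnorm(1, 0, 1)
      out[i, ] <- if (i <= n_informative)
        exp(coupling * env + stats::rnorm(ns, 0, noise_sd))
      else exp(base + stats::rnorm(ns, 0, 1))
    }
    out
  })
  dimnames(m) <- list(ids, sample_ids)
  informative <- ids[seq_len(n_informative)]
  cls <- stats::setNames(ifelse(ids %in% informative, "informative", "noise"),
                         ids)
  tab <- metabolite_table(m, class = cls)
  attr(tab, "informative") <- informative
  tab
}

# Phylogenetically coherent genus labels: average-linkage clustering of the
# patristic distances cut into n_genera groups.
assign_genera <- function(tree, n_genera = 12, prefix = "G") {
  D <- ape::cophenetic.phylo(tree)
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "average"),
                      k = n_genera)
  stats::setNames(sprintf("%s%02d", prefix, cl), names(cl))
}

# Taxonomy data.frame from a genus assignment (higher ranks constant).
genera_to_taxonomy <- function(genera) {
  data.frame(taxon_id = names(genera),
             kingdom = "Bacteria", phylum = "SimPhylum", class = "SimClass",
             order = "SimOrder", family = "SimFamily",
             genus = unname(genera), species = NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Clades (descendant tip sets) of every internal node, as a list.
clade_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  lapply(pp, function(idx) tree$tip.label[idx])
}

#' Build a scenario with a planted keystone clade
#'
#' One phylogenetic clade (labeled as its own genus) is strongly coupled to
#' a divergent two-group environment while every other taxon is sampled
#' neutrally from the metacommunity: the clade is abundant in the high-env
#' group and absent from the low-env group, so it alone carries the
#' variable-selection signal between groups.  Removing that genus should
#' drop the mean betaNTI below the +2 threshold — the flip that
#' [keystone_loo_screen()] detects.
#'
#' @param n_taxa metacommunity size.
#' @param clade_size requested keystone clade size (tips).
#' @param strict if `TRUE`, error when no clade has exactly `clade_size`
#'   tips (listing available sizes); if `FALSE`, use the clade whose size is
#'   closest within `size_range`.
#' @param size_range acceptable clade sizes when `strict = FALSE`.
#' @param n_samples total samples (two equal env groups).
#' @param N reads per sample.
#' @param env_values the two group environments.
#' @param sigma_sel keystone niche breadth (small = tight coupling).
#' @param keystone_meta_frac metacommunity share given to the clade.
#' @param n_genera genus labels for the non-keystone taxa.
#' @param lognormal_sigma metacommunity lognormal sd.
#' @param coupled if `FALSE`, the keystone coupling is disabled (negative
#'   control): the clade is sampled neutrally like everything else.
#' @param seed integer seed.
#' @return A `synthetic_scenario` (see [make_scenario()]) with
#'   `truth$keystone_genus` set.
#' @export
make_keystone_scenario <- function(n_taxa = 200, clade_size = 30,
                                   strict = FALSE, size_range = c(15, 50),
                                   n_samples = 12, N = 1000,
                                   env_values = c(-2, 2), sigma_sel = 0.5,
                                   keystone_meta_frac = 0.4, n_genera = 12,
                                   lognormal_sigma = 2, coupled = TRUE,
                                   seed = NULL) {
  seeds <- derive_seeds(seed, 6)
  tree <- simulate_tree(n_taxa, seeds[[1]])
  clades <- clade_tip_sets(tree)
  sizes <- vapply(clades, length, integer(1))
  ok <- sizes < n_taxa  # exclude the root clade
  pick <- which(ok & sizes == clade_size)
  if (length(pick) == 0) {
    if (strict)
      stop("no clade of size ", clade_size, "; available sizes: ",
           paste(sort(unique(sizes[ok])), collapse = ", "))
    cand <- which(ok & sizes >= size_range[1] & sizes <= size_range[2])
    if (length(cand) == 0)
      stop("no clade with size in [", size_range[1], ", ", size_range[2],
           "]; available sizes: ", paste(sort(unique(sizes[ok])), collapse = ", "))
    pick <- cand[which.min(abs(sizes[cand] - clade_size))]
  } else pick <- pick[1]
  clade <- clades[[pick]]
  meta <- simulate_metacommunity(n_taxa, lognormal_sigma, seeds[[2]])
  names(meta) <- tree$tip.label
  # hand the clade a fixed metacommunity share so it can dominate when favored
  in_clade <- names(meta) %in% clade
  meta[in_clade] <- meta[in_clade] / sum(meta[in_clade]) * keystone_meta_frac
  meta[!in_clade] <- meta[!in_clade] / sum(meta[!in_clade]) * (1 - keystone_meta_frac)
  ns_half <- n_samples %/% 2
  env <- rep(env_values, times = c(ns_half, n_samples - ns_half))
  optima <- stats::setNames(rep(0, n_taxa), names(meta))
  optima[in_clade] <- env_values[2]  # clade favored in the high-env group
  counts <- with_seed(seeds[[3]], {
    vapply(seq_along(env), function(s) {
      w <- meta
      if (coupled)
        w[in_clade] <- meta[in_clade] *
          exp(-(optima[in_clade] - env[s])^2 / (2 * sigma_sel^2))
      stats::rmultinom(1, N, w / sum(w))[, 1]
    }, numeric(n_taxa))
  })
  dimnames(counts) <- list(names(meta), sprintf("S%02d", seq_along(env)))
  table <- asv_table(counts, mode = "counts")
  genera <- assign_genera(ape::keep.tip(tree, setdiff(tree$tip.label, clade)),
                          n_genera = n_genera)
  genera <- c(genera, stats::setNames(rep("G_keystone", length(clade)), clade))
  genera <- genera[tree$tip.label]
  groups <- stats::setNames(rep(c("low", "high"),
                                times = c(ns_half, n_samples - ns_half)),
                            colnames(counts))
  metabolites <- simulate_metabolites(env, seed = seeds[[4]],
                                      sample_ids = colnames(counts))
  structure(list(tree = tree, metacommunity = meta, optima = optima,
                 env = stats::setNames(env, colnames(counts)),
                 groups = groups, communities = table,
                 taxonomy = genera_to_taxonomy(genera),
                 metabolites = metabolites,
                 truth = list(regime = "variable_selection",
                              keystone_genus = if (coupled) "G_keystone" else NA_character_,
                              keystone_taxa = clade,
                              informative_compounds = attr(metabolites, "informative")),
                 seed = seed),
            class = "synthetic_scenario")
}

# Deterministic child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((seed * 7919 + 104729 * seq_len(n)) %% 2147483629L)
}

#' Generate a complete synthetic scenario with known assembly regime
#'
#' Emulates, at the statistical level, the data a pot/soil-culture amplicon
#' study produces: an ultrametric phylogeny, a lognormal metacommunity,
#' Brownian niche optima, local communities assembled under a chosen regime,
#' and a metabolite matrix whose informative compounds track the filtering
#' environment.
#'
#' Regimes:
#' \describe{
#'   \item{neutral}{communities from the neutral stationary distribution
#'     (migration `m`); no selection signal, stochastic partition expected.}
#'   \item{variable}{two sample groups at divergent environments with strong
#'     Gaussian filtering on conserved optima; between-group betaNTI > 2
#'     expected.}
#'   \item{homogeneous}{all samples in one strongly selective environment
#'     (filter centered 1.5 trait sd into the tail), with neutral drift
#'     inside the filtered pool so samples turn over among close relatives;
#'     betaNTI < -2 expected.  Detecting this regime needs a regional pool
#'     much larger than per-sample richness, so it defaults to
#'     `n_taxa = 1000` (see the methods vignette).}
#'   \item{homogenizing}{all communities are multinomial perturbations of
#'     one shared composition (a phenomenological stand-in for mass-effects
#'     dispersal); RCbray near -1 expected.}
#'   \item{gradient}{continuous environment gradient with moderate
#'     filtering; used for driver screening.}
#' }
#'
#' @param regime one of `"neutral"`, `"variable"`, `"homogeneous"`,
#'   `"homogenizing"`, `"gradient"`.
#' @param n_taxa,n_samples,N community dimensions (defaults 200 taxa, 12
#'   samples, 1000 reads).
#' @param m neutral migration probability.
#' @param lognormal_sigma metacommunity lognormal sd.
#' @param sigma_bm Brownian trait sd per unit branch length.
#' @param sigma_sel niche breadth under selection regimes.
#' @param env_values group environments for `"variable"` (length 2) and
#'   `"homogeneous"` (first element).
#' @param n_compounds,n_informative,coupling,noise_sd metabolite generator
#'   settings (see [simulate_metabolites()]); informative compounds track
#'   the environment, so they only carry signal under selection regimes.
#' @param n_genera number of genus labels.
#' @param seed integer seed; scenarios are bit-reproducible given the seed.
#' @return Object of class `synthetic_scenario`: list with `tree`,
#'   `metacommunity`, `optima`, `env`, `groups`, `communities` (counts-mode
#'   [asv_table()]), `taxonomy`, `metabolites`, `truth` (regime label,
#'   informative compound ids) and `seed`.
#' @export
make_scenario <- function(regime = c("neutral", "variable", "homogeneous",
                                     "homogenizing", "gradient"),
                          n_taxa = NULL, n_samples = 12, N = 1000, m = 0.3,
                          lognormal_sigma = 2, sigma_bm = 1, sigma_sel = 0.5,
                          env_values = c(-2, 2), n_compounds = 100,
                          n_informative = 5, coupling = 1, noise_sd = 0.3,
                          n_genera = 12, seed = NULL) {
  regime <- match.arg(regime)
  # homogeneous selection is only expressible against a pool much larger
  # than per-sample richness; all other regimes are fine at 200 taxa
  if (is.null(n_taxa)) n_taxa <- if (regime == "homogeneous") 1000 else 200
  seeds <- derive_seeds(seed, 6)
  tree <- simulate_tree(n_taxa, seeds[[1]])
  meta <- simulate_metacommunity(n_taxa, lognormal_sigma, seeds[[2]])
  names(meta) <- tree$tip.label
  optima <- evolve_optima(tree, sigma_bm, seeds[[3]])
  # standardize the trait scale so the env settings mean the same filter
  # strength on every simulated tree (tip variance varies with tree depth)
  optima <- optima / stats::sd(optima) * 2
  ns_half <- n_samples %/% 2
  env <- switch(regime,
    neutral = rep(0, n_samples),
    variable = rep(env_values, times = c(ns_half, n_samples - ns_half)),
    homogeneous = rep(1.5 * env_values[1], n_samples),
    homogenizing = rep(0, n_samples),
    gradient = seq(env_values[1], env_values[2], length.out = n_samples))
  communities <- switch(regime,
    neutral = simulate_neutral(meta, N = N, m = m, n_samples = n_samples,
                               seed = seeds[[4]]),
    homogenizing = simulate_homogenized(meta, N = N, n_samples = n_samples,
                                        seed = seeds[[4]]),
    homogeneous = {
      # Gaussian filter composed with neutral drift: samples turn over
      # among close relatives inside the filtered pool
      w <- meta * exp(-(optima - env[1])^2 / (2 * (0.6 * sigma_sel)^2))
      w <- stats::setNames(w / sum(w), names(meta))
      simulate_neutral(w, N = N, m = 0.1, n_samples = n_samples,
                       seed = seeds[[4]])
    },
    simulate_selected(meta, optima, env, sigma_sel = sigma_sel,
                      N = N, seed = seeds[[4]]))
  groups <- stats::setNames(
    if (regime == "variable")
      rep(c("low", "high"), times = c(ns_half, n_samples - ns_half))
    else rep(c("g1", "g2"), times = c(ns_half, n_samples - ns_half)),
    colnames(communities))
  metabolites <- simulate_metabolites(env, n_compounds = n_compounds,
                                      n_informative = n_informative,
                                      coupling = coupling,
                                      noise_sd = noise_sd, seed = seeds[[5]],
                                      sample_ids = colnames(communities))
  genera <- assign_genera(tree, n_genera = n_genera)
  regime_label <- switch(regime,
    neutral = "neutral", variable = "variable_selection",
    homogeneous = "homogeneous_selection",
    homogenizing = "homogenizing_dispersal", gradient = "variable_selection")
  structure(list(tree = tree, metacommunity = meta, optima = optima,
                 env = stats::setNames(env, colnames(communities)),
                 groups = groups, communities = communities,
                 taxonomy = genera_to_taxonomy(genera),
                 metabolites = metabolites,
                 truth = list(regime = regime_label,
                              informative_compounds = attr(metabolites, "informative"),
                              keystone_genus = NA_character_),
                 seed = seed),
            class = "synthetic_scenario")
}

# All communities are multinomial resamples of one shared composition drawn
# once from the metacommunity: a phenomenological homogenizing-dispersal
# device (communities far more similar than richness/size-matched nulls).
simulate_homogenized <- function(meta, N = 1000, n_samples = 12, seed = NULL) {
  nt <- length(meta)
  ids <- if (!is.null(names(meta))) names(meta) else sprintf("T%04d", seq_len(nt))
  counts <- with_seed(seed, {
    shared <- stats::rmultinom(1, 10 * N, meta)[, 1] / (10 * N)
    vapply(seq_len(n_samples), function(s)
      stats::rmultinom(1, N, shared)[, 1], numeric(nt))
  })
  dimnames(counts) <- list(ids, sprintf("S%02d", seq_len(n_samples)))
  asv_table(counts, mode = "counts")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("synthetic_scenario (%s): %d taxa x %d samples, N = %d reads\n",
              x$truth$regime, nrow(x$communities), ncol(x$communities),
              sum(x$communities[, 1])))
  invisible(x)
}

#' Write a scenario to a directory of plain-text files
#'
#' Emits `table.tsv` (counts), `tree.nwk`, `taxonomy.tsv`, `metadata.tsv`
#' (env + group), `metabolites.tsv` and `truth.json`.
#'
#' @param scenario a `synthetic_scenario`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asv_table(scenario$communities, file.path(dir, "table.tsv"))
  ape::write.tree(scenario$tree, file.path(dir, "tree.nwk"))
  tx <- scenario$taxonomy
  lineage <- sprintf("k__%s; p__%s; c__%s; o__%s; f__%s; g__%s; s__",
                     tx$kingdom, tx$phylum, tx$class, tx$order, tx$family,
                     tx$genus)
  utils::write.table(data.frame(taxon_id = tx$taxon_id, taxonomy = lineage),
                     file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(scenario$env),
                                env = as.numeric(scenario$env),
                                group = as.character(scenario$groups)),
                     file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_metabolite_table(scenario$metabolites, file.path(dir, "metabolites.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, null = "null")
  } else {
    writeLines(paste0('{"regime": "', scenario$truth$regime, '"}'),
               file.path(dir, "truth.json"))
  }
  invisible(dir)
}
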