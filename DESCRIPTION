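Package: assemblyscope
Title: Ecological Process Partitioning for Microbial Community Assembly
Version: 0.1.0
Authors@R:
    person("assemblyscope", "developers", email = "assemblyscope@example.org",
           role = c("aut", "cre"))
Description: Infers the ecological processes structuring microbial
    communities from amplicon (ASV) count tables and a rooted phylogeny.
    Implements the Sloan neutral community model with 95% prediction
    bands, abundance-weighted beta mean-nearest-taxon distance (betaMNTD)
    with a tip-shuffling null to obtain the beta nearest taxon index
    (betaNTI), the abundance-weighted Raup-Crick metric on Bray-Curtis
    dissimilarity (RCbray), and the five-way partition of sample-pair
    turnover into variable selection, homogeneous selection, dispersal
    limitation, homogenizing dispersal, and drift. Adds a
    leave-one-genus-out keystone screen, a distance-matrix (Mantel)
    screen for metabolite drivers of betaNTI, and a synthetic-data
    generator with known assembly regimes, planted keystone clades and
    planted driver compounds for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    igraph,
    biomformat,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
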