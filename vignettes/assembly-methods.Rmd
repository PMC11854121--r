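---
title: "Models and methods behind assemblyscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind assemblyscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblyscope)
```

# What the package infers

Given an ASV count table, a rooted phylogeny and per-sample metadata,
assemblyscope asks which ecological processes structured the communities:

* **Selection** (deterministic filtering by the environment), split into
  *variable selection* (different environments push communities apart) and
  *homogeneous selection* (a shared environment pulls them together);
* **Dispersal** (organism movement), split into *dispersal limitation* and
  *homogenizing dispersal*;
* **Drift** (undominated stochastic turnover).

Three statistics carry the inference: the Sloan neutral community model fit,
the beta nearest taxon index (betaNTI), and the abundance-weighted
Raup-Crick metric on Bray-Curtis (RCbray).

# The Sloan neutral model

For a taxon with metacommunity relative abundance $p$, the neutral model's
stationary distribution of its local frequency $x$ in a community of $N$
individuals with immigration probability $m$ is
$x \sim \mathrm{Beta}(Nmp,\; Nm(1-p))$.  A taxon is *detected* when its
frequency exceeds a detection limit $d$, so its expected occurrence
frequency across samples is $1 - F_\beta(d;\,Nmp,\,Nm(1-p))$.
`fit_neutral_model()` estimates $Nm$ by least squares of this curve against
the observed detection frequencies, reports $m = Nm/N$ with $N$ the mean
read total, $R^2$ on the frequency scale, and an exact-binomial 95%
prediction band (at `n_samples` trials) that partitions taxa into
above/within/below the neutral expectation.

**Detection limit.** Real detection happens through read sampling: at $N$
reads a taxon at frequency $x$ is seen with probability $1-(1-x)^N$, a
smooth curve whose 50% point is $x = \ln 2 / N$.  The default
`detection = "p50"` uses $d = \ln 2/N$, which makes the fit unbiased on
data generated by the package's own neutral simulator (median fitted $m$
0.298 at true 0.3, $N = 1000$, 200 taxa, 30 samples).  The widespread
single-read convention $d = 1/N$ is available as
`detection = "single_read"`; on read-sampled data it inflates $Nm$ by
roughly 40% at $N = 1000$, which users comparing against published fits
should keep in mind.

# betaMNTD, the tip-shuffle null, and betaNTI

For samples $a, b$ with relative abundances $f$, the abundance-weighted
beta mean nearest taxon distance is

$$\beta MNTD(a,b) = \tfrac12\Big[\sum_i f_{ia}\min_{j:\,f_{jb}>0} d(i,j)
 + \sum_i f_{ib}\min_{j:\,f_{ja}>0} d(i,j)\Big],$$

with $d$ the patristic distance.  A taxon present in both samples
contributes zero — a property worth internalizing, because it means the
entire statistic is carried by *unshared* taxa.  The null model shuffles
taxon labels across the tips of the tree (implemented as a permutation of
the cached patristic matrix, proven in the test suite to equal literal
relabeling) and

$$\beta NTI = \frac{\beta MNTD_{obs} - \mu_{null}}{\sigma_{null}}.$$

betaNTI > 2 flags variable selection, betaNTI < -2 homogeneous selection.
Defaults: abundance-weighted (an unweighted toggle exists), 999
randomizations, seed-controlled.

**The shuffle pool.** `beta_nti(pool = "occupied")` (default) restricts the
regional pool to taxa observed in at least one sample; real tables contain
no all-zero rows, so for them this is the only possible pool, and it makes
removing a never-observed taxon an exact no-op (RNG stream included), which
the leave-one-out screen relies on.  `pool = "table"` treats every table
row as a pool member, which matters for simulations where zero rows encode
a known regional pool (see below).

**Degenerate pairs.** If two samples have identical taxon membership, every
observed and null betaMNTD is zero; the z-score is taken as 0 (no turnover,
no deviation) and classification falls to RCbray.

# RCbray

For each sample pair, `rc_bray()` draws `n_null` pairs of null communities
of matched richness and read total: taxa are chosen without replacement
with probability proportional to occupancy frequency, each drawn taxon is
seeded with one read (so richness matches exactly), and remaining reads are
multinomial with probabilities proportional to metacommunity mean relative
abundance.  With $BC$ the Bray-Curtis dissimilarity on relative abundances,

$$RC_{raw} = \frac{N_{null<obs} + \tfrac12 N_{null=obs}}{n_{null}}, \qquad
RC = 2\,RC_{raw} - 1 \in [-1, 1].$$

Under this **standard convention** RC near $-1$ means the two communities
are far more similar than drift predicts (homogenizing dispersal) and RC
near $+1$ far less similar (dispersal limitation), which is the only
direction compatible with the usual $\pm0.95$ thresholds.  The literal
"count nulls greater than observed" construction is provided as
`convention = "paper_literal"` for auditability; the two conventions are
exact complements ($RC_{raw}^{std} + RC_{raw}^{lit} = 1$).  Ties are judged
at $10^{-10}$.

# The five-way partition

`classify_pair()` applies, with strict inequalities:
betaNTI > 2 &rarr; variable selection; betaNTI < -2 &rarr; homogeneous
selection; otherwise RC > 0.95 &rarr; dispersal limitation, RC < -0.95
&rarr; homogenizing dispersal, else drift.  `partition_fractions()` tallies
labels within groups, between groups, or over all pairs.

# Keystone screening

`keystone_loo_screen()` (1) keeps genera with mean within-sample relative
abundance above 1%; (2) Mantel-tests each genus's pairwise
|&Delta; relative abundance| matrix against betaNTI (a distance-matrix test
is the only correlation construction consistent with pairwise betaNTI);
(3) removes each genus in turn — ASVs dropped, tree pruned, remaining
abundances renormalized per sample so betaMNTD weights stay a proper
distribution — and recomputes betaNTI under the same seed so differences
reflect the removal, not null noise; (4) flags a *flip* when the
full-community mean betaNTI exceeds +2 but falls below it after removal.

# Metabolite driver screening

`bnti_driver_screen()` prefilters compounds at CV > 0.5, then Mantel-tests
each |&Delta; intensity| matrix (and, optionally, Euclidean distances on
z-scored compound-class blocks) against betaNTI.  A compound is selected
when Mantel r > 0.2 and its permutation p, **Benjamini-Hochberg adjusted
across compounds**, is below 0.05.  Two deliberate choices:

* *Spearman by default.*  Intensities are lognormal; a rank-based Mantel is
  invariant to monotone transforms of the intensity scale.
* *BH by default.*  A raw per-compound $\alpha = 0.05$ selects ~5% of
  pure-noise compounds — about 5 false positives per 100 screened — and the
  selected set under a shuffled betaNTI is almost never empty.  Under BH
  the probability of selecting anything from pure noise is about $\alpha$.
  `p_adjust = "none"` restores the raw rule and both p-values are reported,
  so the uncorrected analysis remains reproducible.

# The synthetic world

The generator emulates, at the statistical level, what a pot/soil-culture
amplicon study produces.  Fixed choices, with rationale:

* **Tree**: pure-birth (Yule), unit rate, ultrametric — the standard
  uninformative prior on bacterial phylogenies at this scale.
* **Niche optima**: Brownian motion from root value 0; inside
  `make_scenario()` optima are standardized to trait sd 2 so an environment
  setting imposes the same filter strength on every simulated tree (tip
  variance otherwise varies with tree depth).
* **Metacommunity**: lognormal abundances, log-sd 2 — a typical
  rank-abundance skew for soil communities.
* **Scale**: 200 taxa, 12 samples, 1000 reads by default; every stage runs
  in seconds to minutes on one CPU.  These are two orders of magnitude
  below a real ASV table, which matters for what a green test establishes
  (below).
* **Neutral regime**: the Sloan stationary beta marginals with multinomial
  read sampling ($m = 0.3$), an exact round-trip for the fitted model — not
  a mechanistic birth-death simulation.
* **Variable selection**: two sample groups at environments $\pm 2$ (one
  trait sd apart each from center), Gaussian filter with niche breadth
  $\sigma_{sel} = 0.5$.
* **Homogeneous selection**: one strongly selective environment at $-3$
  (1.5 trait sd into the tail, where Brownian trait slices are
  clade-concentrated), filter breadth 0.3, composed with neutral drift
  ($m = 0.1$) *inside* the filtered pool.  Identical multinomial draws
  would share nearly all abundant taxa between samples and shared taxa
  contribute zero to betaMNTD under observed and null alike, leaving no
  signal carrier; drift makes samples turn over among close relatives,
  which is the signature homogeneous selection + drift leaves in real data.
* **Homogenizing dispersal**: all communities are multinomial perturbations
  of one shared composition — a phenomenological device for mass effects,
  not a mechanistic dispersal model.
* **Metabolites**: informative compounds have log intensity
  $= \text{env} + \mathcal{N}(0, 0.3)$; noise compounds are lognormal.
* **Keystone scenario**: one monophyletic clade of ~30 tips is given 40% of
  the metacommunity mass and coupled tightly ($\sigma = 0.5$) to the
  high-environment group, while all other taxa are sampled neutrally; the
  clade is labeled as its own genus.  At clade 20 / mass 0.3 the
  full-community mean betaNTI occasionally fails to clear +2, making the
  flip undefined; 30/0.4 clears it reliably.

## What a green test does and does not establish

The simulations validate the *machinery* — that each statistic recovers the
regime that generated the data, at a scale two orders of magnitude below a
real study.  They do not establish field performance: real communities mix
regimes across pairs, real phylogenies are deeper and less balanced than
Yule trees, real metabolomes are collinear, and compositional artifacts of
relative abundance are not modeled.

## A scale limit worth knowing about

Homogeneous selection is **not detectable at a 200-taxon pool** in this
world, under any parameterization we searched (filter position 1 to 2 sd
into the tail, breadth 0.15-1.0, migration 0.02-0.3, reads 100-5000,
metacommunity log-sd 1-3, Yule and coalescent trees, weighted and
unweighted betaMNTD): the mean betaNTI plateaus near $-1.5$.  The reason is
structural.  A strongly negative z-score needs (i) observed nearest-taxon
distances much smaller than under the tip shuffle, which requires
per-sample richness to be a small fraction of the pool (otherwise 30-70
random tips out of 200 cover the tree and the null distances are small
too), and (ii) many unshared taxa, so the null standard deviation is small
relative to its mean.  At a 200-taxon pool the two requirements conflict.
At 1000 taxa the same design yields mean betaNTI $\approx -2.5$, so
`make_scenario("homogeneous")` defaults to 1000 taxa, and the
200-taxon acceptance check is expected to stay red — an honest measurement
of the scale limit, not a defect of the statistic.  Real studies, with
thousands of ASVs and per-sample richness a few percent of the pool, sit
comfortably on the detectable side.

Relatedly, the mean betaNTI of a *single* neutral world is not zero: all
sample pairs share one tree and metacommunity draw, leaving a world-level
offset with spread of roughly $\pm 0.4$ at 200 taxa.  Calibration is
therefore assessed as a grand mean over replicate worlds.

# Numerical choices and degenerate inputs

* Column sums of relative tables are checked to $10^{-9}$; Bray-Curtis
  brute-force agreement and betaMNTD oracle agreement are asserted to
  $10^{-12}$.
* Mantel p-values are one-tailed (greater) with the +1 correction;
  Spearman ranks are assigned to the distance-matrix triangle once, which
  is exact because the triangle's multiset is invariant under simultaneous
  row/column permutation.
* Rarefaction is a sequential multivariate hypergeometric draw (without
  replacement), reproducible given a seed, and refuses a zero minimum
  depth.
* `to_relative()` refuses already-relative input, making accidental double
  normalization an error rather than a silent bias.
* All-zero samples, empty taxon/tree intersections, constant variables and
  zero-variance Mantel inputs are hard errors naming the offender.

# Known limitations

* The neutral fit reports no confidence interval on $m$.
* The co-occurrence network is thresholded Spearman correlation without
  multiplicity correction (mirroring common practice); treat edge counts
  qualitatively.
* RCbray inherits the metacommunity definition from the input table (all
  samples in the run); cross-study comparisons need a shared table.
* The keystone flip criterion is one-directional (loss of a variable
  selection signal, mean betaNTI crossing +2 downward).
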