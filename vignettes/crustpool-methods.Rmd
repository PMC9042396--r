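---
title: "Methods: species-pool biogeography, assembly, and co-occurrence in crustpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-pool biogeography, assembly, and co-occurrence in crustpool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

crustpool analyses the biogeography of microbial communities surveyed
across a network of dryland biocrust plots, where each plot is treated as
one species pool (SP). This vignette documents the models and procedures,
the parameters that matter, the synthetic-data generator that backs the
test suite, and the numerical and design choices that were genuinely open.

## The study layout

The reference layout is a ~3,500 km transect of 13 plots with 200 samples:
140 algal (A), 24 cyanobacterial-lichen (C), and 36 moss (M) biocrusts.
Four anchor plots — Fukang (FK), Zhangye (ZY), Minqin (MQ), Shapotou
(ST) — host all three successional stages; the analysis requires every
combined dataset to include at least one anchor and all three stages. In
the synthetic layout the remaining nine plots host stage A only. That
choice is forced by arithmetic: with anchors hosting every stage and all
plots hosting A, the number of admissible k-plot combinations is
`choose(13, k) - choose(9, k)`, which reproduces the published series
202, 589, 1161, 1632, 1680, 1278, 714, 286 for k = 3, ..., 10 exactly.
Any other assignment of C/M crusts to non-anchor plots would change these
counts.

Real plot coordinates are not part of the public record, so the synthetic
transect is an explicit stand-in: plots sit equally spaced on one meridian
(great-circle distance is then linear in latitude and the farthest pair
spans exactly the configured 3,500 km), listed in transect order with the
anchors spread evenly along it (positions 1, 5, 9, 13). Spreading the
anchors keeps anchor membership — and with it sample size and stage
composition — uncorrelated with a combination's geographic extent, which
would otherwise confound the distance-decay regressions.

## Dissimilarities

Two facets of community difference are computed:

* **Taxonomic** — Bray–Curtis, `sum|x_i - y_i| / sum(x_i + y_i)`, on
  per-sample relative abundances by default. Nothing in the workflow
  requires rarefaction; relative abundance avoids committing to an
  arbitrary rarefaction depth, and a raw-count mode is retained because
  the Raup–Crick null operates on counts.
* **Phylogenetic** — weighted UniFrac: each branch contributes its length
  times the absolute difference in the fraction of individuals descending
  from it. The normalized form (divided by `sum l_b (A_b + B_b)`, bounded
  in [0, 1]) is the default so that the two facets are on comparable
  scales in PERMANOVA; the raw form is available.

Shannon diversity uses natural logarithms by default (base 2 exposed).

## Permutation statistics

`permanova()` implements the McArdle–Anderson formulation: Gower-centre
`-D^2/2`, project onto the hat matrix of the predictor's design matrix,
and form `R^2 = SS_model / SS_total`. A categorical predictor uses one-way
dummy coding; a continuous environmental variable is fit as the marginal
two-column model (intercept + variable) — each variable's explanation is a
separate marginal test, matching a per-variable reading of "the
explanation of each environmental variable". Permutations are free
permutations of sample identities, p = (exceedances + 1) / (permutations
+ 1); an exhaustive mode enumerates all n! relabellings for small n and is
used by the test suite as an exact oracle. ANOSIM and the Mantel test wrap
the corresponding vegan routines (average ranks for ties; Spearman by
default for Mantel).

## The species-pool combination framework

For each k in 3..10, every admissible k-plot combination is evaluated:
restrict the samples to the member plots, compute both facet distance
matrices, and record marginal PERMANOVA explanations for the successional
factor (stage labels), the spatial factor (plot labels), and every
environmental variable. A combination's geographic extent is the
great-circle (haversine, sphere radius 6371 km) distance between its two
farthest plots. The **driving force** of a factor is the ordinary
least-squares slope of its R² against extent: positive slopes mean the
factor explains more community variation as the spatial window widens.

The per-variable environmental explanations are aggregated to one number
per combination. The aggregation weighting is genuinely underdetermined,
so three modes are implemented and recorded in output provenance:
unweighted arithmetic mean (default), weights proportional to R²
(`r2-weighted`), and weights proportional to 1 - p
(`significance-weighted`). None is asserted to be the published weighting.

Evaluating all 7,542 combinations with 999 permutations for ~25 variables
on both facets is expensive; `sp_driving_forces()` therefore supports a
seeded random subsample of combinations per k and a reduced permutation
count, while the enumeration counts themselves are always exact. The
package's own validation runs use 10 combinations per k and 199
permutations, which is sufficient to resolve the slope signs.

## Synthetic data and assembly regimes

`simulate_tree()` builds a rooted two-clade phylogeny (an SG1-like and an
SG2-like lineage, mirroring a Nitrososphaeraceae-dominated versus
Haloarchaea-dominated pool): each clade is a random coalescent tree, so
most splits are recent and every tip has close relatives, and the two
clade stems (default length 3) make between-clade divergences much deeper
than within-clade ones. A niche trait evolves on the tree by Brownian
motion — the minimal model that gives the phylogenetic signal the
assembly null models assume — and is standardized.

`simulate_env()` places one latent gradient along the transect; a
salinity-related block (salinity, PO4, silt, WS, pH, AI, MAT, MASD) loads
positively on it, a non-salinity block (Fv/Fm, NH4, ORP, MAP, Alt, WC)
negatively, and the remaining field-catalogue variables are noise. With
the default loading 1 and noise SD 0.3 the two blocks are strongly
anti-correlated, as in the field data that motivated the design.

`simulate_communities()` draws every sample as a multinomial of
`community_size` individuals (default 400) under one of five regimes:

* **Heterogeneous selection** (default strength 30): taxon weights
  `exp(-s (trait - optimum)^2)` with the optimum tracking each sample's
  gradient position across [-2, 2] trait SDs.
* **Homogeneous selection** (default strength 10): one shared optimum,
  placed at the densest mode of the trait distribution. The trait is
  bimodal across the two deep clades, so an optimum midway between the
  modes would select a phylogenetically mixed set and erase the signal
  the regime is supposed to carry.
* **Homogenizing dispersal** (migration 0.97): one realized regional
  community — a single multinomial draw from a log-normal pool — is
  copied into every sample ("mass effects" transport the same community
  everywhere); the remaining 3% of individuals are drawn from log-normal
  plot-local pools.
* **Dispersal limitation** (migration 0): every plot keeps its own
  log-normal pool; communities diverge freely between plots.
* **Drift**: all samples are independent multinomials from equal regional
  weights.

Both selection regimes multiply the niche filter by per-sample
demographic noise: each eligible taxon is retained with probability 0.5
(Bernoulli) and its weight jittered by a mild log-normal (sdlog 0.3).
This term is load-bearing. Without it, all samples under a shared filter
contain the same taxa, every nearest-taxon distance is conspecific (zero)
in both the observed and the null communities, and betaMNTD carries no
selection signal at all. The Bernoulli form — rather than a heavy-tailed
abundance noise — keeps abundances even across the retained taxa, which
tightens the betaMNTD null distribution (its SD is governed by the
effective number of independently placed abundant taxa) and is what makes
|betaNTI| > 2 reachable at desk scale.

An optional `stage_effect` (default 0, i.e. stages have no compositional
imprint) gives the successional factor a genuine effect: under the
selection regimes it offsets each stage's trait optimum by
`stage_effect * (A: 0, C: +1, M: -1)` SDs; under the other regimes it is
a fixed per-stage log-normal tilt on weights. The distance-decay scenario
used to validate the driving-force framework switches it on (0.5),
because a factor that is truly independent of composition has a
scale-invariant expected R² and hence a slope of zero in expectation —
only a real, constant-magnitude successional effect can be progressively
diluted by growing spatial turnover, which is the sign pattern the
framework is meant to detect.

All generators are pure functions of their seed; identical configurations
give byte-identical outputs.

## Assembly partitioning

`bmntd()` computes the abundance-weighted between-community mean
nearest-taxon distance; `bnti()` z-scores it against a null that shuffles
taxon labels across all tree tips (one global shuffle per replicate,
preserving tree shape and community abundances — the standard
"taxa.labels" null). `raup_crick_bray()` ranks the observed raw-count
Bray–Curtis within a null that preserves each sample's richness and total
abundance: taxa are drawn with probability proportional to regional
occupancy, receive one individual each, and the remainder is filled
proportionally to regional relative abundance among the drawn taxa; ties
in the empirical CDF count at half weight, so an observation at the null
median gives RC = 0. Classification follows the conventional thresholds:
betaNTI > 2 heterogeneous selection, < -2 homogeneous selection,
otherwise RC < -0.95 homogenizing dispersal, RC > +0.95 dispersal
limitation, and drift in between. Pairs whose null SD is zero (possible
when two samples share every taxon) are reported as excluded rather than
classified.

The central validation is parameter recovery: for each regime at its
default strengths, the modal classification over 210 sample pairs equals
the generating regime. The recovery suite runs on a 21-sample design
(one A sample per plot, one C and one M per anchor) over a 500-taxon
pool with 199 null replicates; the drift calibration check (95% ± 5% of
pairs inside |betaNTI| < 2) uses a 150-taxon pool and the full 999
replicates. Pool sizes matter here and are deliberate: the betaMNTD null
SD shrinks roughly with the number of independently placed abundant
taxa, so selection signals need the larger pool to clear the ±2
threshold, while the Raup–Crick null is best calibrated when per-sample
counts are singleton-rich (community size comparable to richness), which
the 400-individual default provides at both pool sizes.

## Co-occurrence networks

OTU profiles (relative abundances, prevalence filter 0.2) are correlated
with Spearman's rank correlation by default; two-sided p-values use the
t approximation, adequate at the sample sizes where a network is worth
building. Edges require |r| at or above a threshold (default 0.8) and p
at most 0.05; the edge sign distinguishes coexistence (+) from mutual
exclusion (-). Modules come from greedy modularity maximization on |r|
weights. The web service used in the motivating study selects its
threshold by random-matrix theory and cannot be reproduced bit-exactly;
`rmt_threshold_scan()` provides a documented approximation (spline
unfolding of the thresholded spectrum, chi-squared test of
nearest-neighbour spacings against the Poisson form, smallest
non-rejected threshold), and outputs record which threshold was used.

Topology summaries report node/edge counts, sign percentages, edges per
node, average degree (2E/N), average shortest-path distance over
connected pairs only (disconnected pairs are excluded and counted), and
the modularity of the partition — all on the unweighted graph. Node roles
use the Guimerà–Amaral within-module degree z-score (population SD;
modules with zero SD give z = 0) and participation coefficient, with the
conventional thresholds Zi = 2.5 and Pi = 0.62; "key taxa" are all
non-peripheral nodes, the only reading under which a binary
key/peripheral split can exceed 40% key.

## Numerical choices and degenerate inputs

* Distance matrices are validated to be symmetric within 1e-12 with an
  exactly zero diagonal, and are re-symmetrised after file round-trips
  (writes carry 15 significant digits, so read-write-read is exact to
  1e-12).
* Permutation p-values always use the (count + 1)/(permutations + 1)
  estimator and never return 0.
* PERMANOVA F comparisons use a 1e-12 slack so exhaustive enumeration is
  immune to floating-point ties.
* Empty samples, all-zero abundance vectors, constant predictors,
  singleton ANOSIM groups, single-taxon pools, and missing tree tips are
  hard errors naming the offending object; missing environmental values
  drop samples pairwise for that variable's test only.
* One master seed derives every stage seed additively (`seed + stage
  index`, mod 2^31 - 1), so any pipeline stage can be re-run alone.

## What passing tests do and do not show

The generator emulates the study design's structure (plot/stage layout,
transect geometry, anti-correlated environmental blocks, two-clade pool)
and known assembly mechanisms, but not read-level sequencing noise,
chimeras, OTU-clustering artefacts, compositional depth variation, or the
taxon richness of real amplicon surveys. Passing the recovery suite shows
the estimators respond correctly to the mechanisms they target at desk
scale; it does not certify effect sizes on real data, and the published
real-data slope magnitudes and network tables are not reproducible
without the original sequence data, which the package does not ship.
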