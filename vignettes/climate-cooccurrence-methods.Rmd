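---
title: "Methods: climate-stratified soil co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-stratified soil co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Soil bacterial communities differ systematically between climates, and the
differences show up not only in which taxa are present but in how taxa
co-occur. `climbiome` implements a complete analysis path for asking that
question with amplicon data: starting from an exact-sequence-variant (ESV)
count table and per-sample coordinates, it stratifies samples into
Köppen-Geiger climate zones, filters noise taxa, quantifies diversity and
distance decay, infers one sparse signed co-occurrence network per zone,
compares the networks' topology on an equal footing, and tests which
taxon-taxon combinations carry more edges than chance would allot them.

All stages run identically on real tables (BIOM or TSV) and on the
package's synthetic studies, which come with a known ground-truth
dependence structure so that every downstream claim can be checked against
truth rather than plausibility.

## Filtering cascade

Four filters run in a fixed order, mirroring how a global soil study is
assembled:

1. **Habitat** — keep samples whose EMPO level-3 annotation matches
   `"Soil (non-saline)"`.
2. **Abundance and prevalence** — keep an ESV iff its relative abundance is
   at least `rel_abund_min` (default `1e-5`, i.e. 0.001%; a strict variant
   uses `1e-4`) *and* it is present in at least `prevalence_min` (default
   30%) of samples. Both comparisons are inclusive, and the conjunctive
   (AND) reading is deliberate: either criterion alone lets through either
   rare-but-ubiquitous or abundant-but-sporadic noise. Relative abundance
   defaults to ESV total over grand total; a mean per-sample definition is
   available via `abundance_method = "mean"`.
3. **Kingdom** — keep Bacteria (Archaea are too sparse in soil amplicon
   surveys for stable network estimates).
4. **Zone split** — partition by climate zone, drop zones with fewer than
   `zone_min_samples` (default 5) samples, and drop ESVs with zero total
   count within a zone.

The abundance/prevalence filter is computed once on the full
habitat-filtered table rather than per zone. Filtering within small zones
leaves too few ESVs and destabilises the stability selection downstream;
filtering globally keeps the dominant taxa while still letting each zone's
network be built on the taxa actually observed there.

## Diversity and distance decay

Alpha diversity uses Shannon entropy (nats), the Gini-Simpson index, and
bias-corrected Chao1, `S_obs + F1(F1-1)/(2(F2+1))`. Zones are compared
pairwise with two-sided Wilcoxon tests under a single Holm family. The
package uses the rank-sum (Mann-Whitney) form by default: climate zones
have unequal sample counts, so a paired signed-rank comparison of zones has
no defined pairing. A `paired = TRUE` switch exists for equal-size designs
(and is the default for bootstrap distributions, which *are* paired by
iteration index — see below, where the unpaired test remains the default
for robustness).

Beta diversity is Bray-Curtis. Distance decay is tested by a Mantel
correlation between Bray-Curtis dissimilarity and Vincenty (WGS-84
ellipsoid) geographic distance. The Mantel p-value is two-sided and uses
the add-one convention, `p = (1 + #{|r*| >= |r|})/(1 + B)`, so it can never
be zero; for up to seven samples the permutation null is enumerated
exactly. Near-antipodal coordinate pairs where the Vincenty iteration
fails fall back to the spherical great-circle distance with a warning.

Ordination is non-metric multidimensional scaling on dissimilarity ranks
(Kruskal stress-1, isotonic regression, best of `n_starts = 20` random
initial configurations, deterministic under a seed). The zone effect on
composition is tested by one-factor PERMANOVA on the Bray-Curtis matrix
directly, not on the NMDS coordinates: the ordination is a display device,
the test runs in the full distance space.

## Network inference

The inference stage is the core of the package and is authored here rather
than delegated: counts are mapped by a centered log-ratio (CLR) transform,
`log(x + 1)` centered per sample, which neutralises library-size and
closure effects; conditional dependencies are then estimated by
Meinshausen-Bühlmann neighborhood selection — an L1-penalised regression of
each taxon's CLR profile on all others (via glmnet, standardized
predictors, common penalty scale across nodes).

* **Symmetrisation** — an edge joins i and j when either directed
  coefficient is nonzero (OR rule, the common default; AND available).
* **Sign and weight** — the sign of the mean of the two directed
  coefficients, with an exactly-cancelling pair resolved toward the
  larger-magnitude coefficient; the weight is the mean's magnitude.
* **Penalty grid** — 30 log-spaced values from `lambda_max` (computed from
  the data as the smallest penalty leaving every regression empty, nudged
  a factor 1e-6 upward so the grid's top is an exactly empty model) down to
  `lambda_max / 100`.

The penalty is chosen by StARS stability selection: `n_subsamples = 20`
subsamples of size `floor(10*sqrt(n))` (capped at `n-1`), per-edge
selection frequencies `theta`, instability `D = mean(2*theta*(1-theta))`
over all node pairs, monotonized to be non-decreasing as the penalty
shrinks. The selected penalty is the smallest grid value whose monotonized
instability stays at or below the threshold `beta` — the densest network
that subsampling still reproduces — and the reported network is refit on
the full data there. If no grid point qualifies the sparsest one is
returned with a warning. Two thresholds are in circulation for this kind
of analysis, 0.05 and 0.01; the pipeline default is `beta = 0.05`, the
stricter 0.01 is a parameter away, and the achieved instability is stored
on the network object so the operating point is never implicit.

Two diagnostics accompany every network: an OLS fit of log10 relative
degree frequency on log10 degree (a first-degree polynomial on the log-log
scale; its R² measures how scale-free-like the degree distribution is),
and the Spearman correlation between node abundance and degree (near zero
when hubs are not merely the abundant taxa). The negative-edge fraction is
reported per network.

## Topology comparison and hubs

Global properties are density, global transitivity, Newman modularity of
the fast-greedy partition, and average shortest-path length. All are
computed on the simple, unweighted, sign-stripped graph: fast-greedy
clustering and shortest-path lengths are undefined or unstable with
negative weights, and no principled weighting of lasso coefficients exists
for path metrics. Average path length is taken over reachable ordered
pairs only — subsampled networks are routinely disconnected — and the
reachable fraction is reported next to it so a short path length on a
shattered graph cannot masquerade as integration.

Because zones yield networks of different sizes, raw comparisons of these
properties confound climate with node count. The bootstrap therefore
induces, 100 times, a random node subset of fixed size — when comparing
zones, the smallest zone network's node count — and recomputes all four
properties on the induced subgraph. Zone pairs are compared on these
bootstrap distributions with two-sided Wilcoxon tests, Holm-corrected over
all zone pairs per metric.

Node centralities are unweighted degree, betweenness (fractional credit
for tied shortest paths), closeness within components (with a harmonic
variant), and eigenvector centrality (principal adjacency eigenvector,
unit-max normalised, sign-fixed non-negative). Hubs are nodes whose degree
*strictly exceeds* the empirical 95% quantile (linear interpolation
between order statistics, R's type-7 default) of their own network's
degree sequence — per network, not pooled, so a hub is central relative to
its climate. In a regular graph the rule correctly finds no hubs.

## Overrepresentation

For a zone network with `n_nodes` nodes and `n` edges, each unordered pair
of taxon labels at a rank (same-label pairs and the `Unassigned` category
included — unassigned taxa form real and interpretable edges) defines `K`
node pairs out of `N = n_nodes(n_nodes-1)/2`. The observed edge count `k`
among those `K` pairs is tested against the hypergeometric upper tail
`P(X >= k)` for `X ~ Hypergeom(N, K, n)`: the network's edge budget is
allocated to node pairs as draws from an urn. The urn over *node pairs*
with the realized edges as draws is a modelling choice; it conditions on
both the label composition and the edge budget, which is the natural
exchangeable null when the inference stage fixes how many edges exist.
Holm correction is applied within each zone-by-rank family over the pairs
with `K >= 1`; untestable pairs are excluded from the family rather than
diluting it. A pair is *climate-specific* when it appears as an edge in
exactly one analysed zone.

## The synthetic generator

The generator exists so the recovery claims above are checkable. It is a
normal-to-anything (NorTA) construction: a sparse symmetric
positive-definite precision matrix with hub, band, or random support is
inverted to a latent Gaussian correlation; Gaussian samples are pushed
through the normal CDF and mapped through per-taxon zero-inflated
negative-binomial quantile functions; each sample is then scaled by a
log-normal depth factor and rounded. NorTA matches the generative
assumptions under which MB-on-CLR inference is consistent, which makes the
recovery benchmark a fair test of the estimator rather than of a model
mismatch.

Default marginals were fixed once, as representative of post-filter soil
amplicon data: NB means drawn log-uniformly in [5, 200], dispersion
(size) 1, structural zero inflation 0.15, depth sdlog 0.3, precision
off-diagonals of magnitude 0.3 with 30% of edges negative (matching the
20-40% negative-edge range typical of soil networks), and a diagonal shift
setting the condition number to 100. The depth factor deliberately
correlates all taxa within a sample — that is the compositional distortion
the CLR step must undo, and tests that target the copula alone switch the
depth off.

What the generator does *not* emulate: phylogenetic signal, the extreme
taxon-abundance skew of real surveys, spatial autocorrelation within
zones (coordinates are uniform in a bounding box), or any dependence of
marginals on climate. Passing recovery tests therefore demonstrate
estimator correctness under the stated model, not field performance on
EMP-scale data.

Taxonomy is synthetic (phyla `P01`-`P05`, and so on down seven ranks) with
tunable per-rank unassigned fractions, defaulting to 0/0/0/0.1/0.2/0.4/0.8
from kingdom to species — most soil ESVs lack deep-rank assignments — and
an unassigned rank blanks all deeper ranks.

## Reproducibility model

Every stochastic operation takes a seed; `NULL` leaves the caller's RNG
untouched. The pipeline derives stage seeds, and per-zone seeds, from
`(master_seed, key)` by a small deterministic hash, so adding a zone never
perturbs another zone's draws, and an identical configuration reproduces a
bit-identical result bundle (asserted in the test suite). Each output
table carries the hash of the configuration that produced it.

## Numerical choices and degenerate inputs

* Boundary coordinates on the climate grid resolve to the southern/western
  cell; ocean or uncovered cells return `NA`, never a default code.
* Alpha indices reject all-zero samples; Bray-Curtis refuses a pair of
  all-zero samples by name.
* Mantel refuses constant distance triangles; PERMANOVA refuses a single
  group; NMDS refuses `k >= n`.
* Constant CLR columns are dropped from the regressions with a warning.
* The scale-free fit refuses fewer than five distinct positive degrees.
* Hypergeometric inputs are bound-checked (`0 <= k <= min(K, n)`, `K <= N`).
* An empty network has a defined edge list, round-trips through both file
  dialects, and raises on metrics that need an edge.

Lasso active sets are not exactly nested along the penalty path —
coefficients can drop out as the penalty shrinks — so edge-set
monotonicity holds only approximately; the tests assert near-nesting (at
most a small violation fraction per step) and monotone edge counts rather
than an idealised invariant the estimator does not possess.

## Problem sizes used by the tests

The suite validates recovery at `n = 200` samples by `p = 50` taxa with 5
hubs (median over 5 generator seeds), familywise error with 100 label
shuffles on a 40-node network, exact Mantel enumeration up to `n = 6`, and
an end-to-end three-zone run at roughly 12 samples and 20 taxa per zone.
These sizes were chosen so the full suite exercises every stage, including
stability selection, at desk scale; the same code paths run unchanged on
tables several orders of magnitude larger, where inference is
embarrassingly parallel across zones.

## Known limitations

* The Köppen-Geiger climatology is an input, not a product: zone labels
  depend on which map release the user supplies.
* MB neighborhood selection estimates conditional dependence under an
  approximately Gaussian CLR geometry; heavy zero inflation beyond the
  generator's range degrades it in ways the desk-scale suite does not map.
* Inferred edge signs inherit CLR's closure distortion: a latent positive
  dependence can appear weakened or flipped when a few taxa dominate a
  sample, so negative-edge fractions should be read comparatively, not
  absolutely.
* Modularity and path metrics ignore edge weights and signs by design;
  questions about interaction strength need a different toolset.
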