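---
title: "Detecting biotic homogenization and rare-taxon loss in soil fungal communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting biotic homogenization and rare-taxon loss in soil fungal communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarefungi)
library(dplyr)
```

## The scientific question

Intensive arable farming is suspected of *homogenizing* soil fungal
communities: dominant taxa persist — or become relatively more abundant —
while taxa of restricted distribution ("rare" taxa) become rarer or
disappear. The signature is asymmetric: alpha diversity is lower in arable
fields than in extensively managed grasslands, cumulative rank-abundance
curves for the two land uses coincide at the abundant head but diverge in
the rare tail, and the set of operational taxonomic units (OTUs) found at
only one or two sites shrinks specifically in the arable stratum.

`rarefungi` implements the full statistical pipeline for testing this
hypothesis on an OTU-by-site count table with paired site metadata:
alpha-diversity contrasts, Bray–Curtis ordination with PERMANOVA and
partial Mantel decompositions of geography versus environment, square-root
rank cumulative abundance curves with per-rank Welch tests, an
occupancy-plus-niche-breadth rarity classifier with a permutation null, and
a PCA-based agricultural-intensity index. A synthetic community generator
with a controllable homogenization effect provides ground truth for every
stage.

## Data model and input handling

The central object is a plain tibble: one row per site (`site_id` column),
one integer column per OTU. `read_otu_table()` accepts either on-disk
orientation (`otus_as_rows` flag), enforces non-negative integer counts and
unique ids, and drops empty OTUs/sites with a warning, so every downstream
function can assume positive row totals. Site metadata travels as a tibble
carrying a column→role map (`soil`, `climate`, `mgmt`) so distance and PCA
stages can select variable sets by role rather than by hard-coded names.

Rarefaction (`rarefy()`) subsamples each site without replacement to a
common depth (the study design uses 2000 reads), as a **single draw** with a
required seed. Averaging over repeated draws would shrink the sampling
variance that the downstream tests are calibrated against; a single recorded
draw keeps the pipeline honest and reproducible. Sites below depth are
dropped, never up-sampled. The optional `filter_low_abundance()` pre-step
removes singletons and OTUs below an overall relative-abundance threshold;
whether to apply it before or after rarefaction is left to the analyst, and
niche-breadth and rarity classification are intended to run on the
*unrarefied* table (occupancy at one or two sites is a property of the full
observation effort).

## Alpha and beta diversity

Richness, the natural-log Shannon–Wiener index, and the ACE estimator are
computed per site (`alpha_diversity()`); land-use and country contrasts use
the Kruskal–Wallis rank-sum test with tie correction (`kruskal_wallis()`),
with the all-ties degenerate case defined as H = 0, p = 1 so pipelines never
produce `NaN`. ACE follows the Chao & Lee estimator with the standard rare
cutoff of 10; when every rare read is a singleton the coverage estimate is
zero and the function falls back to bias-corrected Chao1 with a warning.
Because the survey design is unbalanced (156 arable versus 61 grassland
sites), `balanced_site_subsample()` re-runs contrasts on an equal-n random
subset as a robustness check.

Community structure uses Bray–Curtis dissimilarity, classical PCoA (Gower
double-centering; negative eigenvalues are reported, not corrected), and
PERMANOVA with **sequential** (Type-I) sums of squares in the term order
`country, land_use, country:land_use` — with sequential SS the R² values are
order-dependent, and this order asks how much land use explains *after*
geography. Significance is by free permutation of site labels (999 by
default), with no permutation strata. Geographic distance is the haversine
great circle on a 6371 km sphere; environmental distance is Euclidean on
z-standardized covariates (scaled by the population standard deviation, so
two sites on a single covariate sit at z = ±1 exactly — Mantel statistics
are invariant to this convention). Simple and partial Mantel tests permute
the community matrix while holding the geographic and environmental
matrices fixed.

## The rarity toolkit

**Cumulative curves.** Each site's counts are square-root transformed and
sorted in decreasing order; all sites are zero-padded to the table-wide
maximum per-site richness so that rank-wise means are defined everywhere —
without padding, the curve's tail would silently drop exactly the sites
whose missing OTUs are the phenomenon of interest. The per-land-use curve is
the rank-wise mean, accumulated over ranks; its endpoint equals the mean
over sites of the summed square-root counts (an identity the tests verify
exactly). Per-rank Welch tests compare the site-level values between land
uses; raw p values are reported (the analysis is descriptive, rank by
rank), with a Benjamini–Hochberg column available.

**Niche breadth.** For an OTU with proportional occurrence `p_j` over `R`
sites, Levins' measure is `B = 1/Σp_j²` and the standardized breadth is
`Bn = B/R`: 1 for a perfect generalist, `1/R` for a single-site specialist.
The permutation null (`bn_null_test()`, 999 draws) redistributes each OTU's
total reads across sites as a multinomial with probabilities proportional to
site read totals — an abundance-conserving, depth-aware null. The test is
one-sided in the low tail, since specialists are the target. A flag switches
`p_j` to per-site relative abundances for depth-invariant breadth.

**Rarity classification.** An OTU is *rare within a land use* when it is
present at ≤ 2 sites of that land use and its `Bn` — computed across **all**
sites jointly — is below 0.55. The joint-`Bn` gate excludes taxa that are
locally sparse in one land use but widespread in the other; that is what
distinguishes genuine rarity from a sampling edge. `classify_rarity()` also
emits the shared / arable-only / grassland-only partition and
`rare_proportion_by_country()` the per-country rare fractions.
`prevalent_concentration()` reports the smallest number of top OTUs carrying
a target read fraction (default 75%) — the complementary dominance measure.

## Drivers

First- and second-order polynomial models of diversity against latitude or
longitude are compared by AICc (`AIC + 2k(k+1)/(n−k−1)` with k counting
coefficients plus the variance). Covariate PCA prunes one member of every
pair with |Spearman ρ| > 0.95 (keeping the first in column order — the
paper-style covariate blocks are ordered by convention, and which member of
a near-duplicate pair survives is immaterial downstream), then orients PC1
to correlate positively with the first retained variable.
`intensity_index()` collapses the six management variables (insecticide,
herbicide, fungicide application counts, tillage events, maximum tillage
depth, mineral N) into PC1 of their z-scores, sign-oriented so that the mean
loading is positive, min–max scaled to [0, 1]; an optional `crop_diversity`
column is included when present. Spearman correlations link the index to
overall and rare richness.

## The synthetic community generator

`simulate_community()` is first-class, tested code: it generates count
tables whose ground truth is known, so every claim the pipeline makes can be
checked for recovery and for false positives.

Abundance follows a **two-part model**:

* *Occupancy* decays steeply with abundance rank:
  `P(present) = exp(-occupancy_decay · q)` with `q` the rank fraction and
  `occupancy_decay = 4`, putting the rarest pool members at an expected
  occupancy of one to three sites per stratum — the regime the rarity
  classifier targets.
* *Local abundance where present* decays gently: a sorted lognormal profile
  (`lognormal_sigma = 2`) scaled per site and OTU by `exp(N(0, site_sigma))`
  with `site_sigma = 1.5`. Reads are one multinomial draw of the site depth
  (2000) from the present-OTU profile.

This division reflects a robust feature of continental soil-fungal surveys:
regionally rare taxa are rare chiefly because they occupy few sites, yet
remain locally detectable (a handful of reads) where they occur; and which
taxon dominates varies from site to site. A single distribution controlling
both regional and local abundance cannot reproduce that — it either makes
the tail undetectable at realistic depth or hands the depleted tail enough
read mass that curve heads artificially separate.

The **homogenization dial** `h ∈ [0,1]` multiplies occupancy in arable sites
by `(1 − h·q)`: abundant OTUs are untouched, the rarest lose up to fraction
`h` of their occupancy. Acting on occupancy rather than on per-read
abundance is what confines curve divergence to the tail. The default
`h = 0.6` produces a clearly detectable effect at the survey design;
`h = 0` is the exchangeable null used for type-I calibration.

Geography enters through a latitudinal niche kernel: each OTU receives a
preferred latitude and its occupancy is damped by a Gaussian of bandwidth
`geo_bandwidth = 10°` around it, producing community turnover along the
five latitude-ordered country blocks (set `Inf` to disable, which makes
sites fully exchangeable). Soil and bioclimatic covariates are linear in
latitude plus noise; management variables are drawn for arable sites from a
latent intensity `z`, which can optionally feed back on rare-OTU occupancy
(`mgmt_effect`; default 0 so that the `h = 0` configuration is a true null —
a nonzero default would make the "null" communities systematically differ
between land uses).

### What the generator does and does not emulate

It emulates: the unbalanced 156/61 design in five country blocks along a
~3000 km gradient; fixed 2000-read depth; steep dominance with a long
detectable-rare tail; occupancy–abundance correlation; geographic turnover;
covariates collinear with latitude; higher-intensity management in arable
sites. It does **not** emulate: phylogenetic or co-occurrence structure;
temporal dynamics; sequencing error or chimeras; per-site depth variation
(rows sum exactly to depth, so rarefaction is exercised by tests rather than
required by the data); and its pooled dominance is milder than the real
survey's (roughly 90 OTUs carry 75% of synthetic reads, versus 19–30
reported for the real table). Consequently, passing tests demonstrate
correct recovery of *planted* effects under this structure — not that any
particular real-world dataset will show them.

### Truth-record conventions

The truth record stores the per-OTU *true* Bernoulli presences per land use.
A planted rare OTU (for a land use) is one truly present at one or two sites
of that land use; recall is computed **conditional on detection** (≥ 1 read
at ≥ 1 site of that land use), because a truly present tail OTU can draw
zero reads at finite depth — an irreducible property of multinomial
sampling, not a classifier error.

## Numerical choices and degenerate inputs

* Welch tests at ranks where both groups have zero variance return
  `t = 0, p = 1`; Kruskal–Wallis with all-tied values returns `H = 0, p = 1`.
* Permutation p values use the add-one convention
  `(1 + #{extreme}) / (1 + n_perm)`, bounded below by `1/(n_perm+1)`.
* PCoA keeps negative eigenvalues in the report; coordinates use only the
  positive part.
* ACE falls back to bias-corrected Chao1 when the coverage estimate is zero;
  `ACE = richness` when no OTU is rare.
* `intensity_index()` returns all-zero indices if every site is identical
  (degenerate min–max scaling); PCA sign conventions are fixed as described
  so results are reproducible across platforms.
* Constant covariates are dropped with a warning before PCA; sites with
  missing covariates are dropped with a warning before distance or index
  computation.

## Problem sizes used by the test-suite

The acceptance-style checks run at the sizes the methods are designed for:
type-I calibration uses 1000 null communities of 24 sites × 80 OTUs at depth
300 (small communities, because a level is a property of the test, not of
the community size); effect recovery uses 50 full surveys at the study
design (217 sites × 2000 OTUs, depth 2000); oracle-equivalence checks use
4–10 sites where exhaustive permutation enumeration is feasible. These
choices are stated here so a reader can scale them up when exploring.

## Known limitations

* The rarity definition (occupancy ≤ 2 and `Bn` < 0.55) is the study's
  operational one; it captures permanent spatial rarity only — conditionally
  or transiently rare taxa require longitudinal data, out of scope here.
* The multinomial redistribution null for `Bn` conserves OTU totals and
  respects depths, but other nulls (e.g. fixed-richness swaps) answer
  slightly different questions; results near the 0.55 threshold should not
  be over-interpreted.
* Bray–Curtis PERMANOVA is abundance-weighted and therefore nearly blind to
  an occupancy-only homogenization effect — on synthetic data the land-use
  R² is small even at `h = 0.6`. A presence–absence dissimilarity would be
  the sensitive companion analysis.
* The AICc comparison covers polynomial orders 1 and 2 only, mirroring the
  gradient-model usage it supports.
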