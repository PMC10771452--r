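# rarefungi

Statistical tools for detecting **biotic homogenization** of soil fungal
communities across land-use types — the pattern in which intensive arable
farming leaves dominant taxa in place while taxa of restricted distribution
become rarer or disappear.

The package is aimed at microbial ecologists working with OTU-by-site count
tables (e.g. ITS amplicon surveys) and paired site metadata (land use,
country, coordinates, soil chemistry, bioclimatic variables, management
records). It provides, as pipeable data-frame-first functions:

* **Table handling** — validated I/O for count tables, metadata with
  declared column roles, and taxonomy; rarefaction to a fixed depth;
  low-abundance filtering.
* **Alpha diversity** — richness, natural-log Shannon–Wiener, and the ACE
  estimator (Chao & Lee, with a Chao1 fallback in the degenerate
  all-singleton case); Kruskal–Wallis contrasts; balanced subsampling for
  unbalanced designs.
* **Beta structure** — Bray–Curtis dissimilarity, PCoA, PERMANOVA with
  sequential sums of squares, haversine geographic and z-standardized
  environmental distances, simple and partial Mantel tests.
* **Rarity** (the core) — cumulative √-rank abundance curves with per-rank
  Welch tests; occupancy–abundance commonness; Levins' niche breadth
  `Bn = 1/(R·Σp_j²)` with a depth-aware multinomial permutation null; a
  rarity classifier (present at ≤ 2 sites of a land use *and* `Bn < 0.55`)
  with shared/land-use-specific partitioning; read-concentration k.
* **Drivers** — polynomial latitude/longitude models selected by AICc,
  covariate PCA with |ρ| > 0.95 collinearity pruning, PC1 regressions, and a
  PCA-based agricultural-intensity index in [0, 1] with Spearman links to
  diversity.
* **A synthetic survey generator** — 156 arable / 61 grassland sites in five
  latitude-ordered country blocks at 2000 reads per site, with a
  controllable homogenization effect `h` that depletes rare-OTU occupancy in
  arable sites, plus a truth record for recovery testing.

Fitted objects come with broom-style `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures.

## Worked example

```r
library(rarefungi)
library(dplyr)

# a synthetic survey at the study design, homogenization h = 0.6
sim <- simulate_community(sim_config(seed = 42))

alpha <- alpha_diversity(sim$counts) |>
  left_join(sim$metadata, by = "site_id")

alpha |>
  group_by(land_use) |>
  summarise(mean_richness = mean(richness), mean_shannon = mean(shannon))
#>   land_use  mean_richness mean_shannon
#> 1 arable             154.         3.45
#> 2 grassland          165.         3.50

kruskal_wallis(alpha, richness, land_use)
#>   statistic    df p_value n_groups
#> 1      10.8     1 0.00103        2

cc <- cumulative_curve(sim$counts, sim$metadata)
attr(cc, "endpoints")
#>    arable grassland
#>  382.9433  397.2303

cl <- classify_rarity(sim$counts, sim$metadata)
summarise_rarity(cl)
#>   n_otus rare_total_arable rare_total_grassland pct_shared pct_only_arable pct_only_grassland
#> 1   1330               324                  380       75.2            17.4               7.37
```

Read: arable sites average ~7% fewer OTUs (Kruskal–Wallis χ² = 10.8,
p ≈ 0.001); the cumulative √-abundance curve ends lower for arable land
(382.9 vs 397.2) although the curves coincide over the abundant head; and
the rare biosphere — OTUs at ≤ 2 sites of a land use with narrow niche
breadth — is larger in grassland (380 vs 324 OTUs) even though there are
far fewer grassland sites. That asymmetry is the homogenization signature
the generator planted (`h = 0.6`), recovered by the pipeline.

`autoplot(cc)` draws the curve pair; `autoplot(pcoa_ordination(bray_curtis(
sim$counts)), sim$metadata)` shows the country-block structure of the
ordination.

## A note on the science

Levins' standardized niche breadth for an OTU observed with proportions
`p_j` across `R` sites is `Bn = 1/(R·Σp_j²)`: 1 for a taxon spread evenly
over all sites, `1/R` for one confined to a single site. Classifying a
taxon as rare requires *both* low within-land-use occupancy and low `Bn`
computed across all sites jointly — a taxon sparse in one land use but
widespread in the other is not rare. The permutation null redistributes
each OTU's reads as a multinomial proportional to site depths, so
"specialist" means narrower than chance given the sampling effort, not
merely sparse.
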