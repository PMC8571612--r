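# islandisp

Least-cost island-dispersal routes on bathymetric cost surfaces, and the
phylogenetic signal in their characteristics.

## What it is for

Island assemblages are filtered by the sea: which species reach which
islands depends on how far they must travel and how deep the water they
must bypass. If over-sea dispersal ability were a heritable, lineage-level
property, the characteristics of the reconstructed dispersal routes should
show a phylogenetic signal — close relatives with similar route profiles.
`islandisp` implements that analysis for archipelago systems (the
motivating case is the Mediterranean squamate fauna): it is aimed at
comparative biologists and island biogeographers who want a tested,
fully scripted version of the workflow, runnable offline on synthetic
archipelagos with known properties.

The pipeline:

1. **Cost surfaces.** From an elevation grid (ESRI ASCII; negative = sea
   depth), build per-cell resistance under three scenarios: M1 (sea
   costly but crossable, land/sea contrast 5×), M2 (M1 plus a hard
   barrier below −150 m, the last-glacial sea-level minimum, so only
   eustatic-regression routes remain), M3 (sea very unlikely, 100×).
   Resistance rises with distance to coast, sea depth, and land
   elevation.
2. **Routes.** For each species, least-cost travels (8-connected
   Dijkstra, GRASS-style mean-resistance step costs) accrete occupied
   islands nearest-first from the species' origin (mainland for
   colonizers, the largest central island for endemics), plus a
   direction-free minimum spanning tree over occupied sites. Seven
   descriptors per species × scenario: minimum tree, total / average /
   maximum-single travel (km), average and maximum bypassed depth (m),
   and the proportion of travel above the −150 m isobath.
3. **Comparative analysis.** Normality-driven log transforms; correlation
   PCA; Pagel's λ (profile ML, LRT) and Blomberg's K (permutation test)
   per descriptor, with the M1–M3 model uncertainty propagated into an
   interval, and snake/lizard group analyses; phylogenetic linear models
   of each descriptor on spatial centroids, group memberships,
   phylogenetic isolation (10th-percentile divergence time) and total
   length × snake, under eight error structures (BM, OU1, OU2, λ, κ, δ,
   EB, null) ranked by ΔAIC and Akaike weights,
   `w_i = exp(-Δ_i/2) / Σ_j exp(-Δ_j/2)`.

A synthetic-data module (`make_world`, `simulate_tree`,
`simulate_traits`, `assign_occupancy`) generates every input — an
archipelago raster with channels of controlled depth, a dated Yule
phylogeny, traits with controllable λ — so the whole analysis runs with
no downloads and known ground truth.

## Worked example

```r
library(islandisp)
res <- run_pipeline(pipeline_config(seed = 1))
res
#> <pipeline_result> 105 species (103 analysed), scenarios M1/M2/M3
#>   PCA: PC1 0.438, PC2 0.319 (cumulative 0.757)
#>   headline lambda range: 0.000-0.028
#>   best PGLS structure per descriptor: minimum_tree=null, total_travel=OU1,
#>   average_travel=null, max_single_travel=null, average_depth=null,
#>   max_depth=null, prop_travel_150=null
```

105 simulated species on the default six-island basin; 103 enter the
comparative stages (two endemics occupy only their origin island and have
no travels). The first two PCA axes carry 76% of the descriptor variance.
Because synthetic occupancy is independent of the phylogeny, the true
signal is zero — and the pipeline says so:

```r
res$signal[res$signal$statistic == "lambda",
           c("variable", "estimate", "ci_low", "ci_high", "p_value")]
#>           variable estimate ci_low ci_high p_value
#>       minimum_tree   0.0000     NA      NA   1.000
#>       total_travel   0.0285      0  0.0427   0.547
#>     average_travel   0.0000      0  0.0000   1.000
#>  max_single_travel   0.0000      0  0.0000   1.000
#>      average_depth   0.0000      0  0.0000   1.000
#>          max_depth   0.0000      0  0.0000   1.000
#>    prop_travel_150   0.0000      0  0.0000   1.000
```

Headline λ is the mean across the three resistance scenarios and the
interval the scenario min–max; the minimum tree is direction-free, hence
scenario-free with no interval. Model selection likewise favours the
structure with no phylogenetic covariance for six of seven descriptors,
e.g. for average travel:

```r
res$pgls$average_travel$comparison
#>        structure  param  logLik  k    AIC delta_AIC AIC_weight
#> BM            BM     NA -60.983 10 141.97   125.122  3.562e-28
#> OU1          OU1  5e+00   1.251 11  19.50     2.653  1.398e-01
#> OU2          OU2  5e+00   1.251 11  19.50     2.653  1.398e-01
#> lambda    lambda  0e+00   1.577 11  18.85     2.000  1.938e-01
#> kappa      kappa  0e+00 -17.515 11  57.03    40.185  9.899e-10
#> delta      delta  3e+00 -49.846 11 121.69   104.847  9.002e-24
#> EB            EB -1e-05 -60.988 11 143.98   127.131  1.304e-28
#> null        null     NA   1.577 10  16.85     0.000  5.267e-01
```

(λ collapses to its boundary and pays the extra-parameter penalty of +2
relative to the null — the nested-model bookkeeping working as it
should.) The best fit's coefficients expose the spatial structure the
synthetic world really has (occurrence-centroid latitude/longitude
effects on route length), while phylogeny-linked predictors stay flat.

Set `out_dir` in `pipeline_config()` to write every table (metrics,
signal, PGLS selection, PCA), the grid, the tree and a JSON run manifest;
two runs with the same seed produce byte-identical files.

See the vignette (`vignettes/island-dispersal-methods.Rmd`) for the model
in full, every tunable parameter, and known limitations.

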