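# elevrich

Analysis of species richness along mountain elevational gradients:
band interpolation of species elevational ranges, richness–climate
polynomial regression, variance partitioning among climatic predictor
sets, and exhaustive AICc model selection — with a ground-truth
synthetic generator so the whole pipeline is testable end to end.

## Who this is for

Macroecologists working with the classic elevational-gradient design: a
species list with recorded lower and upper elevational limits (e.g.
ferns and lycophytes of a mountain flora), and per-band values of the
standard bioclimatic variables. The package turns those two tables into
the full set of gradient analyses and, just as importantly, lets you
validate every stage on simulated data with known truth before trusting
it on real data.

## The method

The gradient `[0, 5000)` m is tiled into fifty 100-m half-open bands
`[b, b + 100)`. A species with range `[l, u]` occupies every band its
range overlaps with positive length (range interpolation), giving band
richness *S* per taxon group, and species density
*D = S / log₁₀(area km²)* as a species–area check.

All variables (richness included) are z-scored; quadratic terms are
squares of z-scores, re-standardized. For a term subset with *p* slopes,
OLS gives

- *R²adj = 1 − (1 − R²)(n − 1)/(n − p − 1)*,
- *AICc = n log(RSS/n) + 2K + 2K(K + 1)/(n − K − 1)*, *K = p + 2*.

Explained variation is partitioned among predictor sets by partial
regression on the adjusted-R² scale, e.g. for two sets
*unique(A) = R²adj(A∪B) − R²adj(B)* and
*shared = R²adj(A) + R²adj(B) − R²adj(A∪B)*; the three-set analogue
yields seven fractions by inclusion–exclusion, summing exactly to
*R²adj* of the combined model. Best climate models come from fitting all
2¹² − 1 = 4095 subsets of the six variables and their quadratics and
taking the AICc minimum, with relative importance read from absolute
standardized coefficients.

## Worked example

```r
library(elevrich)

cfg     <- synthetic_config(seed = 42)        # Himalaya-like defaults
climate <- generate_climate_table(cfg)
ranges  <- generate_species_ranges(cfg)
scheme  <- make_bands(0, 5000, 100)
pm      <- assign_species_to_bands(ranges, scheme)
profile <- richness_profile(pm, climate$area)
pm
#> Presence matrix: 50 bands x 534 species (27 lycophytes, 507 ferns)
max(profile$S_all); profile$band[which.max(profile$S_all)]
#> [1] 291
#> [1] "2000-2100"
pearson_r(profile$S_all, profile$density)
#> [1] 0.9975
```

Richness is hump-shaped with its maximum just above 2000 m, and density
is nearly perfectly coupled to richness — area differences between bands
cannot affect the conclusions, so richness is the response everywhere.

```r
y <- standardize(as.numeric(profile$S_all))
partition_two(y, c("bio1", "bio6", "bio4"), c("bio12", "bio14", "bio15"),
              climate, labels = c("temperature", "precipitation"))
#> Variance partition (adjusted R2 scale):
#>              fraction  value percent
#>    unique_temperature -0.001    -0.1
#>  unique_precipitation  0.099     9.9
#>                shared  0.884    88.4
#>           unexplained  0.018     1.8
```

Temperature- and precipitation-related variables jointly explain 88% of
the variation in richness; almost nothing is unique to either set —
the signature of predictors that all track elevation. The tiny negative
unique fraction is the usual adjusted-R² artefact and is reported, not
clamped, so the fractions keep summing exactly to the combined model's
*R²adj*.

```r
exhaustive_search(y, climate)
#> Exhaustive AICc search: 4095 candidate models (4095 fitted, 0 skipped)
#> Best model:
#> Polynomial OLS fit: n = 50, 5 term(s)
#>   standardized coefficients:
#>     bio12       0.7052
#>     bio12_sq    0.4594
#>     bio14       0.3023
#>     bio14_sq   -0.1499
#>     bio1_sq    -0.4005
#>   R2 = 0.9859, adj. R2 = 0.9843, AICc = -197.373
#> Relative importance (|standardized coefficient|): bio12 > bio12_sq > bio1_sq > bio14 > bio14_sq
```

The selected model combines a linear precipitation response with a
negative quadratic temperature term — richness rises with rainfall and
responds parabolically to temperature.

`run_all(ranges_csv, climate_csv, analysis_config(out_dir = "out"))`
runs every analysis (3 taxon groups × full/lower/upper segments) and
writes the complete CSV bundle (`richness_profile.csv`, `table1_r2.csv`,
`partition_fig4a.csv` … `partition_fig6.csv`, `table2_best_models.csv`,
`run_log.txt`); `run_synthetic_demo("out", seed = 1)` does the same from
freshly generated inputs in one call.

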