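---
title: "Methods: band richness, climate regressions, variance partitioning and model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band richness, climate regressions, variance partitioning and model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevrich)
```

## The analysis this package implements

Species richness along long mountain gradients is usually hump-shaped: it
rises from the lowlands to a mid-elevation maximum and falls toward the
summits. A standard way to analyse such gradients, used across the
macroecology of ferns and lycophytes (pteridophytes) in particular, is:

1. **Band interpolation.** The gradient is cut into fixed-width vertical
   bands (here 100 m), and each species is marked present in every band
   its recorded elevational range touches. Band richness `S` is the count
   of species present.
2. **Richness–climate regression.** Band richness is regressed on
   bioclimatic variables (bio1, bio4, bio6, bio12, bio14, bio15: mean
   annual temperature, temperature seasonality, minimum temperature of
   the coldest month, annual precipitation, precipitation of the driest
   month, precipitation seasonality), with first- and second-order
   polynomials — a quadratic term captures the parabolic response that a
   hump-shaped richness curve has to any variable monotone in elevation.
3. **Variance partitioning.** The explained variation is decomposed by
   partial regression into fractions unique to, and shared among, groups
   of predictors (temperature vs precipitation; extreme climate vs
   climate seasonality; general vs extreme vs seasonality).
4. **All-subsets AICc selection.** Every subset of the 12 candidate terms
   (six linear + six quadratic) is fitted — 2^12 − 1 = 4095 models — and
   the model with the smallest small-sample-corrected AIC is reported
   with standardized coefficients.

Everything operates on two plain CSV inputs: a species range table
(`species_id, group, elev_min_m, elev_max_m`) and a per-band climate/area
table. A synthetic generator with known ground truth emulates a
Himalayan-style system so the full pipeline can be exercised and
validated without any field data.

## Band construction and occupancy

Bands are half-open intervals `[b, b + width)`. A species occupies a band
when its range overlaps the band with positive length; a point range
(`elev_min = elev_max`) occupies the single band containing the point.
The half-open convention makes boundary records unambiguous: a species
recorded "to 2000 m" occupies `[1900, 2000)` but not `[2000, 2100)`. This
is a design choice — field datasets rarely state their convention — and
the opposite choice would shift occupancy only for ranges ending exactly
on a boundary. Ranges extending past the scheme are clipped rather than
rejected, since real gradients start above sea level (a record from 60 m
sits inside the band `[0, 100)`).

Species density, `S / log10(area in km²)`, is the usual species–area
correction; bands with area at or below 1 km² would make the denominator
non-positive and are flagged with `NA` density. Density is computed for
the richness–density coupling check only; all regressions use richness
as the response, because on realistically smooth area profiles the two
are nearly perfectly correlated (r > 0.99 on the default synthetic
system), so the area correction cannot change any conclusion.

## Standardization and polynomial designs

All variables — response included — are z-scored to mean 0, SD 1
(sample SD, n − 1) before fitting, so slopes are standardized
coefficients comparable across predictors. Quadratic columns are built as
the square of the z-scored variable, then re-standardized, so every
design column is on the same scale. Squaring the raw variable and then
standardizing would give identical R² and AICc (the two columns are
affinely related); only the coefficient scale differs. When a segment of
the gradient is analysed separately, standardization is redone within the
segment: each segment is treated as its own study.

Fits use QR least squares. Rank deficiency is declared when the smallest
singular value falls below 1e−10 times the largest, and the error names
the collinear terms. Adjusted R² is `1 − (1 − R²)(n − 1)/(n − p − 1)`
with `p` the number of slope terms. A residual sum of squares below
1e−20 × TSS is treated as an exact fit (RSS = 0): without this, adding
irrelevant terms to an already-exact model perturbs `log(RSS)` at
floating-point noise level and makes noiseless model selection
nondeterministic.

AICc is `n log(RSS/n) + 2K + 2K(K + 1)/(n − K − 1)` with
`K = p + 2` (slopes, intercept, error variance) — the Burnham–Anderson
convention. Models with `n − K − 1 < 1` score `Inf` and are skipped and
counted in a search rather than raised as errors, because small segments
(20 bands) approach the feasibility bound for large specs. Only AICc
*differences* between models on the same data are meaningful; absolute
values depend on the dropped Gaussian constant.

## Variance partitioning

Fractions are computed by inclusion–exclusion on sub-model fits: for two
sets, `unique_A = R(A∪B) − R(B)`, `shared = R(A) + R(B) − R(A∪B)`; for
three sets, seven fractions derived from the seven sub-model values. Two
choices deserve note:

* **Adjusted R² is the partitioned quantity.** Predictor sets differ in
  size, and raw R² would credit larger sets mechanically; adjusted R² is
  the standard recommendation for that situation (it is also what
  `vegan::varpart` reports, which the test suite uses as an independent
  cross-check). Both scales are a single argument away since any fit
  reports both.
* **Negative fractions are reported as-is.** Small negative fractions are
  a well-known artefact of the adjustment; clamping them to zero would
  break the exact additivity identity (the fractions sum to the combined
  model's adjusted R² to 1e−10 by construction, which the tests assert on
  random data).

All partitioning runs on second-order designs (each variable contributes
its linear and quadratic term), matching how such partitions are done for
hump-shaped responses.

## Exhaustive model selection

All non-empty subsets of the 12 candidate terms are enumerated in a fixed
order (by size, then lexicographically), fitted, and ranked by AICc. A
quadratic term may enter without its linear partner — no marginality
constraint — since best models of this kind do occur in practice for
gradient data. Ties within 1e−9 go to the smaller, then
lexicographically earlier spec, making the search fully reproducible.
Because column subsets of a full-rank matrix are full rank, the rank
check runs once on the full candidate design rather than per subset. The
relative importance of the retained terms is their absolute standardized
coefficient.

## The synthetic study system

The generator's defaults define one emulated system, fixed once:

| quantity | default | what it emulates |
|---|---|---|
| gradient, bands | 0–5000 m, 50 × 100 m | a Himalayan-length pteridophyte gradient |
| species | 534, lycophyte fraction 38/534 | the two taxon groups at realistic proportions |
| richness shape | peak 310 at 2000 m; ends 23 / 5 | hump-shaped richness, mid-elevation maximum |
| range widths | log-normal, meanlog ln 1200 m, sdlog 0.5 | wide elevational amplitudes typical of ferns |
| bio1 | 25 − 5.5 e (°C, e in km), sd 0.3 | a standard lapse rate |
| bio4 | 600 − 60 e + 4 e², sd 8 | seasonality declining, flattening at height |
| bio6 | 12 − 7.5 e + 0.25 e², sd 0.4 | winter minimum dropping faster than the mean |
| bio12 | peak 2500 mm at 2.05 km, sd 30 | hump-shaped precipitation, maximum in the 2000–2100 m band |
| bio14 | 18 − 5.5 e + 0.45 e², sd 0.3 | dry-season rain vanishing upward (floored at 0) |
| bio15 | 70 + 23.9 e − 3.56 e², sd 1.5 | precipitation seasonality rising to ~3350 m, then levelling |
| band area | 5000 × 0.7^e km² | terrain shrinking with elevation |

Range midpoints are drawn by inverse-CDF sampling from a two-sided
Gaussian target curve discretized over band midpoints — the spread below
and above the peak is set so the curve passes through the configured
end-counts — then widths are attached and ranges clipped to the gradient.
Realized band richness is this midpoint density *convolved with the
range-width distribution*, so it is broader than the target curve: with
the defaults the realized peak is ~290–315 species within ±300 m of
2000 m, and the end bands are somewhat richer than the nominal 23/5. The
generator controls the shape exactly and the realized counts only
approximately; tests therefore assert the shape (unimodality, peak
location) rather than exact counts. The log-normal width distribution is
a stand-in: field datasets do not report a distributional form for range
amplitudes.

The curvature terms in the climate profiles matter: if all monotone
variables were exactly linear in elevation, their z-scored columns would
be identical up to noise (pairwise r ≈ 0.999) and no model-selection
procedure could tell them apart. Real elevational profiles differ in
shape, and the distinct curvatures keep the six variables statistically
distinguishable. Climate noise is independent across bands — the
regression analyses themselves assume no elevational autocorrelation —
and each generator draws from its own stream derived from the single
seed (offsets 0, 1, 2 for climate, ranges, and recovery noise), so the
tables are independently perturbed yet jointly reproducible.

What the generator does *not* emulate: spatially explicit (2-D)
structure, phylogenetic structure in range placement, elevational
autocorrelation of climate noise (an AR(1) knob could be added, but the
analyses assume none), and observational error in range limits. Passing
tests on this system therefore validate the *computational pipeline* —
interpolation, fitting, partitioning, selection — under known truth, not
the ecological claims one would make from field data.

## Parameter-recovery experiments

`generate_recovery_dataset()` plants a known response law — expected band
richness as a linear combination of standardized climate columns — adds
Gaussian noise, rounds to integer counts, and *constructs species ranges
whose occupancy reproduces those counts exactly* (rises in the richness
skyline open species, falls close the most recently opened ones; each
species is a contiguous run of bands). The truth record then scores any
downstream run.

The default law, `E[S] = 150 − 35·z(bio1²) + 25·z(bio12)` with noise
SD 10 species, has the canonical structure of gradient systems: a
parabolic response to temperature and a linear response to annual
precipitation. `run_recovery_study()` repeats this over seeded
replicates and scores how often the exhaustive search (i) includes both
true terms in the best model and (ii) gives the quadratic temperature
term a negative coefficient. The study amplifies the climate noise SDs
threefold relative to the emulation defaults: recovery requires an
identifiable design, and with near-noise-free profiles the climate
columns are so collinear that distinct variables are interchangeable
proxies — a property of the gradient, not of the search. With that
design the true terms are recovered in ≥ 90% of 50 replicates and the
quadratic is negative in ≥ 95%, the two rates the acceptance suite
asserts. With the amplified noise the law's tail can dip slightly below
zero at the sparse top bands; expected richness is floored at zero
there, the analogue of counts bottoming out.

## Problem sizes and determinism

The test and acceptance runs use the study-scale sizes throughout: 50
bands, 534 species, the full 4095-model search per group × segment, 50
recovery replicates, 1000-range interpolation oracles, and 100-instance
fit oracles. One full search takes well under a second; the complete
suite a couple of minutes. Every stochastic step is seeded explicitly,
and `run_all()` output bundles are byte-identical across reruns with the
same inputs and configuration (no timestamps are written).

## Known limitations

* The lycophyte analyses include zero-richness bands (lycophytes can be
  absent from high bands); whether such bands should be excluded is a
  judgement call field studies rarely state. Both are possible here by
  subsetting, the default is to include.
* Richness is modelled with Gaussian OLS, not a count GLM; that is the
  classic practice this pipeline mirrors, appropriate when band richness
  is large, but Poisson-type error would be preferable near the gradient
  ends if inference on individual coefficients mattered.
* Whether partition percentages are best reported on the raw or adjusted
  R² scale is a live methodological question; the package computes
  adjusted by default and raw is recoverable from any fit.
* No spatial-autocorrelation correction is offered: bands are treated as
  exchangeable observations, as the partial-regression framework
  assumes.
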