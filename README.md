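# foragemap

Core foraging areas from GPS telemetry and imaging spectroscopy, and a
statistical comparison of what sympatric ungulates forage on.

## The problem

Chamois, ibex and red deer share alpine valleys at high densities, and
classical diet analyses (micro-histology of faecal pellets) often find no
difference in what they eat at the plant-family level. But forage *quantity*
(fresh-weight biomass, g m⁻²) and *quality* (nitrogen content, % dry mass)
vary at scales of metres in alpine grassland, below the resolution of
vegetation-type maps. `foragemap` implements the analysis chain that asks
the finer question — do the species concentrate their foraging on different
resources? — by combining three pieces:

1. **GPS screening** — fixes resampled to a common 4 h interval, capture
   days trimmed, and location errors flagged by a two-stage rule (distance
   from a 20 h windowed median with μ = 50 km / Δ = 200 km; turnaround
   spikes with both speeds > α = 1.5 km/h and turn cosine < −0.97).
2. **Behavioural maps (time-local convex hulls)** — the time-scaled distance
   TSD = √(Δx² + Δy² + (s·v_max·Δt)²) joins space and time; local convex
   hulls around each fix (a-method: nearest neighbours up to cumulative TSD
   *a*) are sorted by revisitation rate (number of separate visits under a
   12 h inter-visit gap, max-normalised: NNSV) and merged until 30% of fixes
   are enclosed. That 30% isopleth is an animal's **core foraging area
   (CFA)**. `s` is tuned to 60% time-selected hulls, `a` to stabilise the
   isopleths' edge:area ratio before an area jump.
3. **Resource maps and the comparison** — every simple ratio index
   (SRI = band i / band j) of a hyperspectral cube is ranked by correlation
   with field plots; the best 100 pairs compete across linear, exponential
   and quadratic forms under AIC with leave-one-out validation (Theil's U,
   RMSE, % within 20% RMSE); non-grassland is removed by fully constrained
   linear spectral unmixing (grass fraction ≥ 0.5). Raster cells under the
   CFAs then feed a baseline-category multinomial logit (chamois reference,
   BiomRS = biomass/100): five candidate models compared by ΔAIC and
   likelihood-ratio tests, with Hosmer–Lemeshow calibration, per-logit ROC
   AUC, and a ±6 m buffer sensitivity analysis on the CFA delineation.

Because collar data and flight data of such studies are not public, the
package includes a first-class synthetic-data module — trajectories with
scheduled patch revisitation, hyperspectral scenes with planted band-ratio
relations and endmember mixing, and species cell-use with planted
preference coefficients — so every stage is validated against known ground
truth. See the methods vignette (`vignettes/foragemap-methods.Rmd`) for the
models, parameter defaults and design decisions.

## Worked example

One fully synthetic study — scene, plots, spectral models, unmixing,
trajectories, screening, hull maps, extraction, model selection,
diagnostics, sensitivity — in a single deterministic call:

```r
library(foragemap)
cfg <- study_config(
  scene = scene_config(n_rows = 250, n_cols = 250, n_bands = 12,
                       biomass_field = list(mean = 295.26, sd = 230.10, corr_length = 30),
                       n_field = list(mean = 2.11, sd = 0.53, corr_length = 30),
                       seed = 3),
  n_plots = 51, n_individuals = 1, n_patches = 4, patch_radius = 80,
  margin_cells = 55, seed = 3)
rep <- run_study(cfg)
print(rep)
#> Synthetic foraging study report
#>   scene: 250 x 250 x 12 (cells x cells x bands), res 2 m
#>   spectral models:
#>     biomass  pair (4/3) exponential  Theil's U 0.022 adj R2 0.996 RMSE 19.1
#>     nitrogen pair (5/6) polynomial2  Theil's U 0.006 adj R2 0.997 RMSE 0.0248
#>   observations: 12303 cells; best model: interaction
#>   AUC logit 1 (chamois vs ibex): 0.837  logit 2 (chamois vs red deer): 0.8
#>   buffer sensitivity: min p = 0.558
```

Reading this: the spectral search recovered the planted band pairs and
functional forms (Theil's U near 0 means near-perfect prediction; the
biomass RMSE of 19 g m⁻² is small against a valley mean of ~295 g m⁻²).
The interaction model (df = 8) won the AIC comparison:

```r
rep$comparison$table[, c("form", "df", "delta_aic", "lrt_p")]
#>            form df delta_aic lrt_p
#> 1     intercept  2  6670.598     0
#> 2  biomass_only  4  3304.468     0
#> 3 nitrogen_only  4  3914.636     0
#> 4  main_effects  6    98.162     0
#> 5   interaction  8     0.000    NA
```

AUCs of 0.84 and 0.80 mean the fitted model discriminates ibex and red deer
CFA cells from chamois cells well, and the buffer sensitivity (minimum
Holm-adjusted p = 0.56 across all 16 coefficient-equality tests) says the
conclusions do not hinge on the exact ±6 m delineation of the CFAs.

Individual stages are plain functions: `resample_fixes()`,
`screen_errors()`, `select_s()`, `select_a()`, `tlocoh_isopleths()`,
`export_cfa()`, `rank_sri()`, `fit_sri_models()`, `unmix_lsu()`,
`predict_raster()`, `extract_cells()`, `compare_models()`,
`hosmer_lemeshow_logit()`, `auc_logit()`, `buffer_sensitivity()`.
Interchange is plain text: trajectory CSV, polygon GeoJSON, scene JSON.

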