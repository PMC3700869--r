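# arcrange

Home-range size, seasonal resource selection and landscape structure for
Arctic grizzly bears — an end-to-end, fully tested R implementation of
the question *what drives variation in female home-range size where
cover heterogeneity is low?*

The package is aimed at movement and spatial ecologists who want each
stage of this classic analysis as a testable, scriptable function rather
than a chain of GIS operations:

- **Home ranges.** 95% fixed-kernel ranges with least-squares
  cross-validated bandwidths (`lscv_bandwidth()`, `kernel_ud()`,
  `isopleth()`), 100% minimum convex polygons (`mcp()`), and the ≥60%
  study-area inclusion rule (`study_area_filter()`).
- **Seasons.** Ward clustering of standardized bi-weekly cover-use
  profiles with Duda–Hart / pseudo-t² stopping (`build_profiles()`,
  `ward_cluster()`, `choose_k()`), forced to contiguous calendar blocks.
- **Resource selection.** Use–availability logistic regression with a
  per-animal random intercept and water as the reference cover
  (`fit_rsf()`), relative selection indices
  RSI = exp(|β|) (`rsi_from_coefficient()`), reclassification into
  highly-selected / matrix / water (`selection_map()`), and Manly
  selection-ratio validation w = u/a with a Wald test
  (`selection_ratio()`).
- **Landscape metrics** inside each range: proportional selected cover,
  landscape shape index LSI = 0.25·E/√A, edge density, Shannon–Wiener
  diversity (`range_metrics()`).
- **Model comparison.** log10 home-range area against reproductive
  status and landscape covariates: collinearity screening (|r| ≥ 0.6,
  VIF > 10), AICc with Akaike weights, the 10% confidence set, per-term
  importance weights, conditional model averaging and a random-intercept
  check (`fit_candidates()`, `confidence_set()`,
  `importance_weights()`).
- **Synthetic data.** Categorical landscapes (smoothed-field
  quantile thresholding, `generate_landscape()`) and cover-biased
  Metropolis random-walk GPS tracks with known seasonal preferences
  (`simulate_tracks()`), so every stage is testable without field
  telemetry. `run_pipeline()` chains all stages from one (optionally
  YAML) config.

Rasters are read and written as plain-text ESRI ASCII grids with a JSON
class legend sidecar (`read_raster()` / `write_raster()`); fixes as CSV
with ISO-8601 timestamps; polygons as GeoJSON.

## Worked example

Selection-table arithmetic — the relative selection index of a cover
whose fitted log-odds coefficient (vs. the water reference) is 3.20, and
of a strongly avoided cover at −2.31:

```r
library(arcrange)
rsi_from_coefficient(3.20)
#> [1] 24.5
rsi_from_coefficient(-2.31)
#> [1] 10.1
```

The first cover is selected about 24 times more readily than the
reference; the second is *avoided* (RSI reports magnitude, so the
highly-selected class additionally requires a positive coefficient).

Candidate-model comparison on a simulated 43-range covariate table whose
areas are generated from reproductive status plus the season-1 landscape
shape index:

```r
d <- simulate_range_table(seed = 1)
models <- list("null model" = character(0), rs = "rs", s1lsi = "s1lsi",
               "rs+s1lsi" = c("rs", "s1lsi"))
fit_candidates(d, models)
#> <hr_model_set> 4 candidate(s), n = 43, lmer (ML)
#>       model k   logL   AICc dAICc w   R2
#>    rs+s1lsi 3  26.64 -46.66   0.0 1 0.91
#>       s1lsi 2  14.15 -24.01  22.7 0 0.84
#>          rs 2 -23.91  52.11  98.8 0 0.06
#>  null model 1 -25.14  52.38  99.0 0 0.00
```

The generating model (`rs+s1lsi`) is top-ranked with essentially all the
Akaike weight; `k` follows the convention that a status factor counts as
one parameter and variance components are uncounted, and `R2` is the
squared correlation between fixed-effect predictions and observed log10
areas (0 for the null by construction).

A full synthetic run — landscape, 30 collared females, three programmed
seasonal preference regimes — and its recovery:

```r
rep <- run_pipeline(pipeline_config(list(
  seed = 11, landscape = list(n_rows = 256, n_cols = 256))))
rep
#> <pipeline_report>
#>   animals: 30  fixes: 16793  ranges kept: 30
#>   seasons: k = 3 ; breaks after weeks 31, 39
#>   ...
```

The clustering recovers the three programmed seasons and their
week-31/39 breaks blind.

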