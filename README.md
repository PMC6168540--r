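# medfire

Non-stationary climate–fire modelling of Mediterranean summer burned area.

`medfire` is for fire ecologists and climate-impact statisticians who want
to calibrate drought–burned-area regressions per eco-region, ask how the
drought sensitivity of fire varies with the background climate, and project
summer burned-area changes at the 1.5, 2 and 3 °C global warming levels —
with the stationarity assumption both kept and relaxed, and with full
uncertainty propagation across a climate-model ensemble and the regression
bootstrap.

## The model

For eco-region *i* and summer *t* (June–September), burned area BA follows

```
log BA(i,t) = β₁(i) + β₂(i)·SPEI_sc,m(i,t) + β₃(i)·T(t) + ε(i,t)        (calibration)
```

where `SPEI_sc,m` is the Standardized Precipitation-Evapotranspiration
Index accumulated over `sc ∈ {3, 6, 12}` months ending at anchor month `m`
(searched over March–September), standardized against a fixed 1971–2000
reference window via a PWM-fitted log-logistic distribution, with potential
evapotranspiration from the modified (precipitation-aware) Hargreaves
formulation. Predictor selection uses a spatially coherent permutation test
(one shared year-shuffle across regions per iteration), Benjamini–Hochberg
FDR control, and an argmin-correlation rule; `β₃` enters only when a
Mann–Kendall test finds a trend; coefficients come from IRLS with a Tukey
bisquare weight and a shared-sequence pairs bootstrap (B = 1000).

The spatial variation of drought sensitivity is modelled across regions as

```
β₂(i) = γ₁ + γ₂·X(i) + ε(i)                                             (space-for-time)
```

with `X` a long-term climate normal (annual mean temperature `Ty` and five
alternatives), filtered by correlation significance and a Moran's I
residual check. Projections then compare, per climate-model member and
30-year warming window (earliest window whose global-mean anomaly versus
1881–1910 reaches the level):

* **SM** (stationary): `log BA = β₁ + β₂·SPEI`,
* **NSM** (non-stationary): `log BA = β₁ + (γ₁ + γ₂·X_future)·SPEI`,

as percent changes of mean predicted burned area relative to the reference
window, pooled over members (RCM uncertainty) or members × bootstrap
replicates (ALL), with linear-scaling bias correction, extrapolation
policies (extrapolate / exclude / constrain), and a stippling rule for
regional significance and agreement.

Real fire and climate archives are out of scope; a synthetic-data module
generates climate panels, pseudo-RCM ensembles and burned-area series with
known ground truth, so the entire chain is testable end to end.

## Worked example

```r
library(medfire)
library(dplyr)

clim  <- simulate_climate(n_regions = 12, start_year = 1950,
                          end_year = 2015, seed = 42)
truth <- simulate_truth(clim, seed = 43)   # plants β₂ = -1.62 + 0.057·Ty
ba    <- simulate_burned_area(clim, truth, seed = 44) |>
  filter(year %in% 1985:2011)

fits <- calibrate_fire_models(ba, clim, B = 500, seed = 45)
glance(fits)
#> # A tibble: 1 × 6
#>   n_regions n_modelled mean_r mean_cv mean_beta2 frac_trend
#>       <int>      <int>  <dbl>   <dbl>      <dbl>      <dbl>
#> 1        12         12  0.894   0.871     -0.714      0.167

normals <- compute_normals(clim, c(1971, 2000))
bm <- fit_beta2_model(fits, normals, covariate = "Ty", seed = 46)
bm
#> beta2 ~ Ty: gamma1 = -1.875, gamma2 = 0.07567 (r = 0.58, p = 0.052; Moran p = 0.902)
tidy(bm)
#> # A tibble: 2 × 4
#>   term   estimate conf.low conf.high
#>   <chr>     <dbl>    <dbl>     <dbl>
#> 1 gamma1  -1.87    -2.79      -1.02
#> 2 gamma2   0.0757   0.0188    0.137
```

All twelve regions acquire a model with the true predictor; the mean
in-sample correlation (0.89) and its cross-validated counterpart (0.87)
say the drought signal explains most interannual burned-area variance in
this low-noise world, and the cross-region fit recovers the planted
(γ₁, γ₂) within its bootstrap intervals. `run_fire_pipeline()` runs the
same stages plus ensemble projection from a single seeded config and
returns summaries, regional classifications and a manifest;
`plot_change_summary()`, `plot_beta2_relation()` and `plot_spei_series()`
draw the standard figures.

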