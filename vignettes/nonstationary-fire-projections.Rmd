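---
title: "Non-stationary climate-fire models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-stationary climate-fire models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Summer wildfire activity in Mediterranean-type ecosystems is tightly coupled
to drought: hot, dry summers cure fuels and burned area (BA) rises sharply.
Statistical fire projections usually assume this coupling is *stationary* —
that a region's drought sensitivity stays fixed as the climate warms. But
drought sensitivity itself varies in space with climate: cooler, wetter,
more productive regions burn more strongly in response to a drought of given
severity than hot, fuel-limited ones. If warming pushes a cool region toward
the climate of today's hot regions, its drought sensitivity should drift
toward theirs. `medfire` implements both views side by side and quantifies
what the difference does to burned-area projections at 1.5, 2 and 3 degrees
of global warming.

## The model chain

**Drought index.** Drought is measured by the Standardized
Precipitation-Evapotranspiration Index, `SPEI(sc, m)`: the climatic water
balance `PRE - PET` accumulated over `sc` months (3, 6 or 12) ending at
anchor month `m`, standardized to a unit normal through a three-parameter
log-logistic distribution (generalized-logistic parametrization, fitted by
unbiased probability-weighted moments) on a fixed 1971-2000 reference
window. The same reference-fitted parameters are applied to future periods,
which is what makes future SPEI values comparable to the historical
climate; out-of-support values are capped at +/-3 and flagged. PET uses the
modified (Droogers-Allen) Hargreaves formulation, which needs only monthly
mean temperature, diurnal range, latitude (through extraterrestrial
radiation) and precipitation — the default because precipitation enters the
formulation; classic Hargreaves is available for sensitivity.

**Per-region regression.** For each eco-region `i` and summer `t` (JJAS),

log BA(i,t) = b1(i) + b2(i) * SPEI_sc,m(i,t) + b3(i) * T(t) + eps(i,t).

The predictor `(sc, m)` is chosen per region from the grid
`sc in {3,6,12} x m in {March..September}`: one-tailed (negative)
significance of each candidate correlation is assessed with a permutation
test that applies the *same* year shuffle to every region within an
iteration — this preserves the spatial dependence of the field and is the
standard guard against spurious field significance — followed by
Benjamini-Hochberg FDR control across all region-by-candidate tests, and
the most negative significant correlation wins. Regions with no significant
candidate stay unmodelled and are excluded from everything downstream. The
linear time term is included only when a Mann-Kendall test (tie-corrected,
continuity-corrected) finds a significant trend in either log BA or the
selected SPEI series; it absorbs slowly varying non-climate influences such
as changing fire management. Coefficients are estimated by iteratively
reweighted least squares with a Tukey bisquare weight (tuning constant
4.685, 95 % Gaussian efficiency), OLS-started; parameter uncertainty comes
from a pairs bootstrap (1000 replicates) that again shares one resampled
year sequence across regions; skill is reported in-sample and by
leave-one-out cross-validation.

**Cross-region sensitivity model.** The drought sensitivities `b2(i)` are
regressed on long-term climate normals, `b2(i) = g1 + g2 * X(i) + e(i)`,
with `X` one of `Ty, Ts, PREy, PREs, P-PETy, P-PETs` (annual/summer mean
temperature, precipitation, water balance). Candidates are kept when the
fitted-versus-observed correlation is significant (permutation test) and
the residuals show no spatial autocorrelation (Moran's I with
inverse-distance, row-standardized weights and permutation p-values), then
ranked by correlation. This space-for-time relation is the engine of the
non-stationary model.

**Projection.** For every climate-model member, monthly variables are
bias-corrected by linear scaling (ratio factors for precipitation and the
derived PET, additive offsets for temperature, per calendar month, fitted
on 1971-2000); the raw pathway stays available as a robustness check.
Member SPEI is standardized against the member's own reference window.
Warming windows are the earliest 30-year spans whose global-mean
temperature anomaly versus 1881-1910 reaches 1.5, 2 or 3 degrees; a member
that never reaches a level contributes a "not reached" record, not an
error. The stationary model (SM) predicts BA with the calibrated `b2`; the
non-stationary model (NSM) replaces the future-window sensitivity by
`g1 + g2 * X_future`, with `X_future` the covariate normal over the warming
window. Percent change is the change of mean predicted BA between the
warming window and the reference window; the noise term is excluded from
both sides (its lognormal retransformation factor cancels in the ratio) and
the trend term is deliberately dropped, so the projections respond to
climate only. Uncertainty pools members ("RCM" mode) or members times
bootstrap replicates ("ALL" mode; NSM replicates pair each regression
replicate with a resampled-regions replicate of `(g1, g2)`). Regions are
classified by the stippling rule: significant-and-agreeing when at least
50 % of simulations show a significant change (two-sided Wilcoxon rank-sum
between the 30 reference and 30 future predicted BA values; rank tests are
invariant under the monotone exponential transform, so one test per member
and region suffices) and more than 66 % agree in direction.

## The synthetic study design

Real burned-area archives and climate-model ensembles are deliberately out
of the build-test loop; the package ships a generator whose defaults *are*
the study conditions, so every stage can be verified against a known truth:

* 40 eco-regions on a south-north line (latitudes 36-46, longitudes -8 to
  25), long-term mean annual temperature graded from 17 downward by 0.3
  degrees per region — reproducing the cross-region temperature spread the
  sensitivity model feeds on.
* Monthly climate with a summer-peaking temperature cycle (amplitude 8),
  wet-winter/dry-summer gamma-distributed precipitation (January mean 95
  mm, July 25 mm, coefficient of variation 0.55 — gamma keeps precipitation
  non-negative and realistically skewed, which the log-logistic SPEI fit
  needs), and a positive diurnal-range cycle for the Hargreaves input.
* Burned area generated from the log-linear model itself with
  `b2(i) = -1.62 + 0.057 * Ty(i) + scatter(sd 0.1)`, intercepts near 6
  log-hectares, noise sd 0.3, true predictor `SPEI(3, August)`. All
  planted sensitivities are negative (drought increases fire).
* Pseudo-RCM members: 9 per scenario, two scenario families (a moderate one
  whose warming plateaus at 2070 and a high one that warms throughout, rates
  0.02-0.026 and 0.028-0.04 degrees/yr — chosen so every member reaches the
  1.5 and 2 degree levels but only the high scenario reaches 3, the
  ensemble structure the warming-level sampling is designed for),
  member-specific additive
  temperature biases (sd 1.5) and multiplicative precipitation biases
  (0.8-1.25), regional warming at 1.2 times the global anomaly and
  precipitation declining 4 % per global degree — a Mediterranean-like
  amplification and drying. Members inherit the observed panel's realized
  historical variability, so bias-correction identities can be checked
  exactly.

What the generator does *not* emulate: spatial correlation of weather noise
across regions, storm-scale persistence, autocorrelated fire-weather
regimes, and non-climate drivers (ignition, land use, suppression). Passing
tests therefore demonstrate the statistical machinery is correct under the
stated generative model, not that the fitted numbers transfer to any real
fire archive.

## Numerical choices and edge cases

* Calibration runs on 27-year windows (1985-2011-like); the SPEI reference
  and the percent-change baseline are 1971-2000. The percent-change
  baseline itself is a design choice — model-predicted BA is used in both
  numerator and denominator so the retransformation factor cancels.
* IRLS: bisquare `c = 4.685`, coefficient-change tolerance 1e-8, up to 300
  iterations. The robust MAD scale is re-estimated only during the first 50
  iterations and then frozen: the discrete jumps of the median otherwise
  lock rare resamples into a two-cycle that never meets a tight tolerance.
  Bootstrap replicates use 1e-6/150 — percentile intervals are insensitive
  below that.
* Permutation p-values use the add-one convention `(r + 1)/(B + 1)`; with
  B = 1000 and heavy multiplicity the attainable FDR-adjusted minimum
  matters, so significance searches should not be run with B much below
  500.
* Degenerate bootstrap resamples (a single year drawn throughout) are
  redrawn, keeping the replicate count fixed; IRLS failures inside
  replicates are recorded as missing and dropped from summaries.
* Eco-region SPEI, when gridded inputs are aggregated upstream, is the
  average of grid-point SPEI (not SPEI of averaged balances); at the
  region-level grain of this package the distinction is moot but the
  convention is documented here.
* The anchor-month search window is March-September of the fire year — the
  "previous spring through summer" reading of the predictor family.
* The NSM reference side defaults to the historically calibrated `b2`
  (`future_only` mode); a `both_sides` mode evaluates the spatial relation
  in both windows. The equation is printed without window subscripts in the
  source literature, so both conventions are defensible; `future_only`
  keeps the reference prediction anchored to the fitted model, and the
  degenerate-NSM identity (g2 = 0 collapses onto SM) holds exactly in
  `both_sides` mode.
* Extrapolation policies: `extrapolate` (default), `exclude` (drop regions
  whose future covariate normal leaves the cross-region calibration range)
  and `constrain` (clip future covariate and SPEI to historical extremes).
* Spatial averaging uses equal region weights by default; area or
  burned-area weights can be supplied.
* Moran's I weights are inverse centroid distance, row-standardized, with
  permutation inference — the test is named, not specified, in the source
  literature, so this is the package's choice.
* The Benjamini-Hochberg step-up procedure is the FDR control; the
  shared-sequence null limits the dependence-induced inflation BH is
  sensitive to.

## Problem sizes used in the shipped tests

The test suite exercises the chain at the study design's native scale where
the statistics demand it (200 datasets of 40 regions by 27 years for the
recovery and null checks, 1000 bootstrap/permutation replicates) and at
reduced scale (12-15 regions, 2-5 members, B = 300-500) for structural and
end-to-end checks. `scripts/acceptance.R` runs the full default design: 40
regions, 18 members, B = 1000, three warming levels.

## Known limitations

* The permutation and bootstrap machinery treats years as exchangeable;
  serial correlation in drought indices is only partially absorbed by the
  trend term.
* Percentile bootstrap intervals at n = 27 are mildly anticonservative;
  coverage near 0.93 rather than 0.95 is expected and tested for.
* The NSM transfers a spatial relation into time; that substitution is an
  ecological hypothesis, not a statistical consequence, and nothing in the
  package can validate it from a single realization.
* PET options are limited to the Hargreaves family; no Penman-Monteith, no
  sub-monthly resolution, and no precipitation-only index.
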