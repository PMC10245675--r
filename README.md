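# mpmigrate

Move-persistence models, route metrics and stop-over detection for
marine animal telemetry.

## What this package is for

Satellite tags on migrating marine mammals (the motivating system is
narwhal, *Monodon monoceros*, on their autumn migration out of the
Canadian Arctic) produce irregular, error-prone location fixes.
`mpmigrate` turns those raw fixes into answers to three questions:

1. **Which route did each individual take?** Fixes are cleaned (Argos
   class-Z removal, an iterative 30 km/h speed filter), regularised with
   a continuous-time correlated random walk state-space model, and
   classified nearshore vs offshore by mean distance to the coastline
   (70 km rule) inside a migration-corridor box; daily step lengths and
   a 14-day straightness index summarise each track's geometry.
2. **What drives behaviour along the route?** A move-persistence
   mixed-effects model links the autocorrelation of movement
   (γ ∈ (0,1); high = directed transit, low = area-restricted search)
   to environmental covariates on the logit scale:

   logit(γ<sub>t,k</sub>) = (β₀ + b<sub>0,k</sub>) + Σₙ βₙ m<sub>t,n,k</sub> + ε<sub>t</sub>,
   &nbsp; b<sub>0,k</sub> ~ N(0, σ<sub>b</sub>²), ε<sub>t</sub> ~ N(0, σ<sub>γ</sub>²)

   with per-individual random intercepts, step process
   s<sub>t</sub> = γ<sub>t</sub> s<sub>t−1</sub> + N(0, σ<sub>p</sub>² I),
   covariates ice concentration, depth, bathymetric slope and SST, and
   distance-to-shore (linear + quadratic) in every candidate model.
   Candidates are ranked by AIC with a within-2-ΔAIC parsimony rule.
3. **Where are the stop-overs?** The fitted model predicts daily γ
   surfaces at 0.016°, masked to a 70% kernel-density polygon and to the
   covariate ranges experienced along the tracks; the two-month median
   surface is thresholded at γ ≤ 0.5 to extract stop-over regions, and
   per-individual residency times count 4-h positions inside buffered
   regions.

A synthetic world (coastline, shelf, fjord/canyon pockets, daily ice and
SST, and telemetry simulated from the exact process the model assumes,
with known parameters) backs every stage with ground truth.

## Worked example

Published per-individual migration summaries for 21 satellite-tagged
narwhal ship with the package:

```r
library(mpmigrate)
tab <- narwhalMigrationSummary()
si  <- tab$total_km / tab$sum_steps_km           # straightness index
round(mean(si[tab$route == "offshore"]), 3)      # 0.385  (n = 6)
round(mean(si[tab$route == "nearshore"]), 3)     # 0.622  (n = 15)
w <- welchT(tab$si[tab$route == "offshore"],
            tab$si[tab$route == "nearshore"])
# Welch t = -2.61, df = 8.24, p = 0.030
```

Offshore migrants have markedly more tortuous tracks (mean straightness
0.385) than nearshore migrants (0.622), and the unequal-variance
comparison is significant at the 5% level — the geometric signature of
two different migration tactics.

A miniature end-to-end run on synthetic data:

```r
env <- generateEnvFields(seed = 1)           # bathymetry, ice, SST fields
set.seed(42)
sim <- simulateTrack(env, id = "demo", start = c(-72.5, 72),
                     startTime = as.POSIXct("2017-10-01", tz = "UTC"),
                     nSteps = 600, intervalH = 1,
                     beta = c(intercept = 2.2, ice_conc = -0.4,
                              slope = -0.5),
                     sigmaGamma = 0.5, sigmaP = 0.7,
                     obs = defaultObsModel())
fx <- new("TelemetryFixes", fixes = sim$fixes)
fx
#> TelemetryFixes: 438 fixes, 1 individual(s)
#>   span 2017-10-01 to 2017-10-26 00:07:25 UTC
fx <- speedFilter(dropClassZ(fx))            # 398 fixes survive
tr <- fitCTCRW(fx, intervalH = 4)
tr
#> RegularTrack demo : 151 positions at 4 h
covs <- buildCovariates(list(tr), env)
covs
#> CovariateMatrix: 151 positions, 1 individual(s)
#>   scaled: ice_conc, bathy, slope, sst, dist, dist2
```

The 25 days of heavy-tailed Argos-style fixes (up to several km of
error) are smoothed to a regular 4-h track with ~1.7 km RMSE against the
simulated truth.  From here, `fitMPM()` fits the behavioural model,
`selectModel()` ranks covariate subsets, `kdePolygon()` +
`medianGammaSurface()` + `stopoverRegions()` map stop-overs, and
`residencyTime()` counts the days spent in them; `simulatePopulation()`
builds whole multi-individual studies.  The methods vignette
(`vignettes/move-persistence-migration.Rmd`) documents the model,
estimation, defaults and design choices.

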