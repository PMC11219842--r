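# vertmig

Tools for studying elevational (altitudinal) migration of alpine ungulates
from GPS collar data and gridded environmental fields, written for movement
ecologists working on systems like Sierra Nevada bighorn sheep, where
animals track snowmelt and green-up waves between low winter and high
summer ranges. Real collar data for such endangered populations are
restricted, so the package pairs every analysis stage with a seeded
synthetic-data generator carrying known ground truth, making the whole
chain testable end to end.

## What it implements

**Land-surface phenology.** Per-pixel NDVI and fractional-snow-cover (FSC)
series are fit to the double logistic

```
f(t) = 1 / (1 + exp((xmidS - t)/scalS)) - 1 / (1 + exp((xmidA - t)/scalA))
```

giving green-up timing (`xmidS` of the NDVI curve), snowmelt timing
(`xmidA` of the FSC curve on an Aug-15 snow-year axis), relative and
absolute NDVI, and signed days-since-event covariates. NDVI is rescaled to
its own 2.5/97.5 percentile range and median-smoothed before fitting.

**Terrain.** 4-neighbour slope and aspect, cosine-transformed aspect
(north = +1, south = -1), a 30° escape-terrain mask, and exact Euclidean
distance transforms (distance to escape terrain, distance to snow).

**Migration classification.** An elevational net-displacement analogue:
daily elevation use is compared across resident (constant), disperser
(single logistic rise delta, theta, phi) and migrant (rise plus return)
curves by AIC, with 500 m displacement and 21-day residence thresholds.
Migration duration is the 5-95% traverse time `2 * phi * ln(19)`; under
7 days is a fast migrant. Strategy and rate switch statistics come with
standard errors over individuals.

**Integrated step-selection analysis.** 12-h rarefaction, step building,
gamma/von Mises movement-kernel MLE, 30 available endpoints per used step,
the field-standard covariate transforms (z-scores, log1p, hot-day 75th
percentile, elevation-by-hot-day and elevation-by-raining interactions),
and conditional logistic regression by an in-package Newton solver with
analytic derivatives. Variance comes both model-based and as a CR1
cluster-robust sandwich with t(G-1) intervals; QIC
(`-2 loglik + 2 tr(I_model V_robust)`) compares the full model against
terrain/weather/snow/forage-only blocks; group models and fivefold x 100
rank-frequency cross-validation round out the toolkit.

**Trends.** Random-intercept linear mixed models (lme4 underneath, ML by
default) with conditional R² and herd-year timing summaries
(snowmelt-to-green-up lag, share of migrations preceding green-up).

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on every fit, and `autoplot()` for the main result
types. Gridded data travel as a light matrix-backed `raster_grid` class
with plain-text Esri ASCII grid I/O; fixes as CSV.

## Worked example

Simulate a small synthetic study with known selection coefficients, then
recover them with the full pipeline (rarefaction, kernel fit, available
sampling, conditional logistic fit with movement-adjustment terms):

```r
library(vertmig)
library(dplyr)

sc <- migration_scenario(seed = 7, grid_size = c(50, 50), cell_size = 200,
                         n_animals = 20, n_steps = 120)
dem    <- make_landscape(sc)
fields <- make_dynamic_fields(sc, dem)
world  <- prepare_sim_world(sc, dem, fields)
pop <- simulate_population(sc, world,
                           class_probs = c(resident = 1, fast = 0, slow = 0),
                           t0_doy = 200, seed = 7)

st   <- build_steps(rarify_track(pop$fixes))
kern <- fit_movement_kernel(st)
#> <movement_kernel> gamma(shape 1.515, scale 217.4 m), von Mises(mu 0.049, kappa 0.158)

stra <- sample_available(st, kern, k = 30, extent = dem, seed = 1)
covs <- c("elevation_z", "rel_ndvi", "log1p_dist_escape")
X <- bind_cols(stra, as_tibble(sim_covariates(world, stra$x, stra$y, stra$doy, covs)))
X$log_sl <- log(pmax(X$sl, 1e-6)); X$cos_ta <- cos(X$ta)

fit <- fit_clogit(X, c(covs, "sl", "log_sl", "cos_ta"))
tidy(fit, exponentiate = TRUE)
#>   term              estimate std.error statistic  p.value conf.low conf.high exp.estimate
#> 1 elevation_z       -0.774    0.262       -2.96  8.1e- 3  -1.32     -0.226          0.461
#> 2 rel_ndvi          -0.323    2.39        -0.135 8.9e- 1  -5.33      4.69           0.724
#> 3 log1p_dist_escape -0.780    0.0198     -39.4   1.1e-19  -0.822    -0.739          0.458
#> 4 sl                 0.00125  0.000139     8.95  3.0e- 8   0.00095   0.00154        1.00
#> 5 log_sl             0.449    0.0386      11.6   4.3e-10   0.368     0.530          1.57
#> 6 cos_ta             0.374    0.0398       9.41  1.4e- 8   0.291     0.458          1.45
```

The generating coefficients were elevation_z = -0.5, rel_ndvi = +1.0,
log1p_dist_escape = -0.8. Distance to escape terrain is recovered sharply
(-0.78, exp(beta) = 0.46: selection strength roughly halves per log-metre);
elevation lands within its interval; relative NDVI is weakly identified at
this toy scale -- its interval spans the truth but is wide, because
within-stratum greenness contrast is small on a 10-km landscape -- a useful
reminder that iSSA coefficient precision is covariate-contrast-limited, not
just sample-size-limited. The positive `log_sl`/`cos_ta` terms absorb the
tentative-kernel mismatch, which is exactly their job.

Classification works from the same fix tables:

```r
pr   <- simulate_elevation_profile("migrant", delta = 1200, theta = 150,
                                   phi = 4, noise_sd = 50, seed = 7)
fits <- fit_elevation_models(pr$day, pr$elevation)
classify_strategy(fits, pr$day)
#>   class   model_class gamma0 delta theta   phi theta2  phi2 criterion
#>   migrant migrant      1803. 1195.  150.  3.95   270.  4.20     2869.
migration_window(150, 3.95)   # duration 23.3 d -> a slow migrant
```

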