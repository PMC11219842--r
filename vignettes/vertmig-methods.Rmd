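---
title: "Models and methods behind vertmig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vertmig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertmig)
```

vertmig implements the analysis chain used to study elevational (altitudinal)
migration of alpine ungulates such as Sierra Nevada bighorn sheep: satellite
phenology extraction, terrain covariates, migration classification from GPS
collar tracks, and integrated step-selection analysis (iSSA). Because real
collar data for endangered populations are restricted, the package ships a
seeded synthetic-data module that generates landscapes, dynamic environmental
fields and tracks with known ground truth, so every stage can be validated
end to end. This vignette explains the models, the parameters that matter,
the numerical choices, and what the synthetic validation does and does not
demonstrate.

## Land-surface phenology

Seasonal greenness and snow cover are summarised per pixel by the
double-logistic curve

$$
f(t) \;=\; \frac{1}{1 + \exp\!\big((\mathrm{xmidS} - t)/\mathrm{scalS}\big)}
      \;-\; \frac{1}{1 + \exp\!\big((\mathrm{xmidA} - t)/\mathrm{scalA}\big)},
$$

where `xmidS` and `xmidA` are the ordinal days of the rising and falling
inflections and `scalS`, `scalA` their timescales in days. For NDVI, `xmidS`
is green-up timing; for fractional snow cover (FSC, 0–100%), fitted on a
"snow year" running 15 August–14 August so every series starts snow-free,
`xmidA` is snowmelt timing. Days-since covariates are signed differences
from these dates and are deliberately uncapped: the selection responses they
feed are monotone over the observed range.

NDVI series are first floored at zero, rescaled so the 2.5th/97.5th
percentiles map to 0/1 (linear-interpolation quantiles, the single quantile
convention used package-wide, including the hot-day threshold), then smoothed
with a width-3 moving median. The rescaling bounds `lo`/`hi` are retained so
curve predictions can be mapped back to the raw index ("absolute NDVI");
the curve prediction clipped to $[0,1]$ is "relative NDVI".

Fitting is bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`): inflections bounded to the observed span, timescales
to $[0.5, 60]$ days; starting inflections come from the extreme first
differences of a median-denoised copy of the series, with a second
half-amplitude-crossing start as a fallback (noisy daily series can
otherwise hijack the initial values with a single jump). Failures and fits
pinned at bounds return `converged = FALSE` rather than an exception —
a monotone series genuinely lacks a senescence signal and should be flagged,
not fitted. Pixels that fail yield missing covariates, and any stratum
touching a missing covariate is dropped whole to keep choice sets balanced.

Two accuracy properties are worth separating. Given a rescaled series, the
fitter recovers a noiseless curve to machine-level precision and, under
Gaussian noise of 0.05 with 16-day sampling, green-up timing to within
±3 days for ≥95% of pixels (daily FSC at 5% noise: snowmelt within ±1 day).
The percentile *rescaling itself*, however, carries a structural bias of
roughly −2 days on green-up timing at 16-day sampling: clipping at the
2.5/97.5 percentiles leaves the rescaled plateau slightly below 1, and the
unit-amplitude curve compensates by shifting its rise. This is a property of
this rescaling convention, persists no matter how many years
support the percentiles, and should be kept in mind when interpreting
absolute (rather than relative or trend) timing estimates.

## Terrain covariates

Slope and aspect use the 4-neighbour (rook) rule: central differences over
the east–west and north–south neighbours, one-sided at grid borders so
planar surfaces are exact everywhere. Aspect is the compass bearing of the
downslope direction; its cosine scores north-facing slopes +1 and
south-facing −1, and flat cells (undefined aspect) get the neutral value 0
to avoid biasing the north–south axis. Escape terrain — slopes where
bighorn are relatively safe from predators — is slope ≥ 30°, boundary
inclusive. Distances to escape terrain and to dense snowpack (FSC ≥ 50% by
default; the cutoff is a configurable knob since "dense snowpack" has no
canonical threshold) use an exact two-pass Euclidean distance transform,
verified against brute-force nearest-cell search in the tests. All grids are
single-band, square-celled and projected; distances are Euclidean metres.

## Migration classification

Seasonal elevation use (daily-averaged DEM elevation under each
animal-year's fixes) is compared against three mean structures fitted by
nonlinear least squares: a constant (resident), a single logistic rise of
height $\delta$ centred on day $\theta$ with timescale $\phi$ (disperser),
and a rise-plus-return with a second logistic at $\theta_2 > \theta$
(migrant). Candidates are compared by Gaussian AIC, ties breaking toward the
simpler model. Winners are then subjected to the biological thresholds:
$\delta \ge 500$ m between seasonal ranges and at least 21 days of modelled
residence on each range, with residence counted *in temporal order* — the
low range before $\theta$, the high range between $\theta$ and $\theta_2$.
The ordering matters: without it a pure descent, which the migrant curve can
mimic with its first inflection pinned before the data, would pass both
residence checks. Uphill dispersers join the migrant class (the analysis
concerns uphill spring migration); sub-threshold candidates are demoted to
resident.

Migration timing is $\theta$; migration rate is $\phi$. The informal
notion of "how long the migration lasted" is made precise as the 5–95%
logistic traverse time $2\phi\ln 19$, the standard logistic-width
convention, monotone in $\phi$: under 7 days is a fast migrant, otherwise
slow. Between-year switch rates (strategy: resident↔migrant; rate:
fast↔slow among migratory year-pairs) are per-individual fractions of
consecutive-year changes, summarised as a mean ± SE over individuals.

## Movement model and design assembly

Tracks are rarefied to 12-h fixes by greedy slot filling with a ±2 h
tolerance (the fix nearest each slot wins); a slot with no fix is a gap, and
no step spans a gap, so steps of more than 14 h never form. Steps carry
Euclidean lengths and signed turning angles (three consecutive fixes; the
first step of each burst has none). The population movement kernel is a
gamma distribution on step lengths (maximum likelihood via Newton on the
digamma equation; zero lengths are replaced by half the minimum positive
length for fitting only) and a von Mises distribution on turning angles
(circular-mean direction; concentration by inverting $A(\kappa)$ with a
Bessel-ratio Newton refinement, capped at 500 for degenerate samples).

Each used step is matched with $K = 30$ available endpoints drawn from the
fitted kernel along the previous heading; off-grid draws are retried a
bounded number of times and unresolvable strata are dropped whole.
Covariates are extracted at endpoints by nearest cell on each product's
native grid: terrain static, phenology timing fixed within a year, FSC,
distances, NDVI metrics and weather daily. Transforms follow the field-standard
conventions: z-scores for elevation, slope and temperature pooled over the
full design; natural log(value + 1) for precipitation and the two
distances; "hot day" = startpoint temperature above the 75th percentile of
that animal-year's startpoint temperatures; "raining" = startpoint
precipitation > 0 mm; elevation-by-hot and elevation-by-raining
interactions formed after z-scoring. Individuals are optionally equalised by
seeded subsampling to the minimum per-individual stratum count.

## Conditional logistic fitting, variance, and model comparison

The iSSA likelihood is the stratified conditional (softmax) likelihood
$\sum_s [\beta^\top x_{\text{used},s} - \log \sum_j \exp(\beta^\top x_{js})]$,
maximised by Newton–Raphson with the analytic gradient and Hessian and
step-halving on overshoot (convergence: relative log-likelihood change
below $10^{-10}$ or 50 iterations; the likelihood is concave, and the final
gradient norm is checked in the tests). A design with no within-stratum
variation at all is returned as $\hat\beta = 0$ at the uniform-choice
likelihood $-\sum_s \log n_s$; partial within-stratum rank deficiency is an
error. Perfect separation is detected as a runaway coefficient (|β| > 30 on
the working, typically z-scored, scale) — including the case where the
likelihood plateaus at numerical zero — and reported, never returned as a
quiet "converged" fit.

Model-based variance is the inverse observed information. The headline
standard errors are a cluster-by-individual sandwich with the CR1
finite-cluster factor $G/(G-1)$, and robust Wald intervals use $t_{G-1}$
critical values — the standard pairing for the few dozen clusters typical
of collar studies. QIC is $-2\ell + 2\,\mathrm{tr}(I_{\text{model}}
V_{\text{robust}})$, which reduces to AIC when the two variances agree;
it drives the comparison of the full model against terrain-, weather-,
snow- and forage-only blocks, and the same machinery fits the population
subsets (females, males, residents, migrants, fast and slow migrants), with
coefficients reported raw and exponentiated.

The movement-adjustment columns `sl`, `log_sl` and `cos_ta` are computed on
every stratum row. Including them corrects the bias that arises because the
tentative kernel is estimated from *selected* steps; in the package's own
recovery study, omitting them inflated habitat-coefficient bias by an order
of magnitude. The default covariate list mirrors the classic
terrain/weather/snow/forage set, and the adjustment terms are ordinary
columns the caller adds to the model.

Cross-validation is fivefold at the individual level (stratum level, with a
warning, when there are fewer individuals than folds) with 100 repetitions
by default: each held-out used step is ranked by predicted selection weight
among its 31 stratum members, and the fold score is the Spearman correlation
between rank class and the frequency of used steps in that class. The score
is near zero in a no-selection world and climbs toward 1 under strong,
correctly specified selection — but note it needs enough held-out strata
(roughly 400 per fold) to populate all 31 rank classes before values above
0.9 are reachable; small validation sets plateau lower because empty
low-rank classes tie.

## Trend models

Phenology and timing trends use Gaussian random-intercept mixed models with
one or two crossed factors (herd unit, year), fit by maximum likelihood by
default (REML optional) through lme4. Conditional $R^2$ is the
variance-partition definition
$(\sigma^2_{\text{fixed}} + \sum_k \sigma^2_k) / (\sigma^2_{\text{fixed}} +
\sum_k \sigma^2_k + \sigma^2_\varepsilon)$. Wald z inference is reported —
no small-sample degrees-of-freedom corrections — and decade-scale rates are
10 × the per-year coefficient. Zero-variance factors collapse the fit to
OLS, which the tests check to $10^{-6}$. Herd-year summaries include timing
means and SDs, the snowmelt-to-green-up lag, and the proportion of
migrations preceding mean green-up, restricted to herd units with at least
3 individuals tracked in at least 5 years.

## The synthetic world

The generator's defaults describe an eastern-Sierra-like escarpment and are
fixed once: a 1500–4000 m west–east gradient with seeded sinusoidal ridges
(so 30°+ escape terrain exists, as on a real escarpment with incised
canyons); snowmelt inflection at calendar day 41 at the bottom, delayed
0.02 days per metre of elevation; green-up lagging snowmelt by 136 days and
senescence following 110 days later; NDVI on a 16-day composite grid and FSC
daily, mirroring the differing native resolutions of the real products;
temperature following a seasonal cosine with a −6.5 °C/km lapse rate and a
shared daily anomaly (so two pixels on the same day differ exactly by the
lapse term); sparse region-wide precipitation events (daily probability
0.06, exponential magnitudes averaging 8 mm). Tracks use a gamma(2, 300 m)
step-length kernel and von Mises(κ = 0.5) turns at 12-h intervals, with
softmax choice over 100 proposal endpoints — deliberately different from
the analysis constant K = 30, so estimation never sees the generator's own
choice set. Simulated migrants acquire their uphill pull through a logistic
ramp added to the elevation coefficient at their own θ and φ, which gives
the classifier genuine rise-and-settle profiles to work on.

What passing tests on this world demonstrate: correctness of the estimators
and their calibration (coverage, null behaviour) when the data-generating
process matches the model family. What they do not demonstrate: robustness
to sensor artifacts, cloud contamination, irregular fix success, behavioural
states, or habitat–kernel interactions absent from the generator. Real
MODIS/Landsat processing, reprojection and gap-filling are out of scope.

## Problem sizes and reproducibility

The validation studies run at fixed reference sizes chosen to estimate each
property precisely at desk scale: 50 strata × 31 candidates against a
derivative-free oracle; 200 replicates of 30 animals × 40 steps for
coverage and bias; 500 pixels for phenology recovery; 100 animal-years for
classification; 200 replicates for mixed-model slope recovery; 500–1000
permutations for null calibration. Every stochastic stage takes an explicit
seed, and `scripts/acceptance.R` recomputes the full battery from a single
`--seed` argument. Gridded inputs and outputs travel as plain-text Esri
ASCII grids and CSV fix tables, so a whole analysis can be reconstructed
from text artifacts alone.
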