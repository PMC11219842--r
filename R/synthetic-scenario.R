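#' Define a synthetic elevational-migration study scenario
#'
#' Bundles every parameter of the synthetic world: the landscape geometry,
#' the elevationally delayed snowmelt/green-up phenology, lapse-rate weather,
#' the movement kernel, and the selection coefficients used to simulate
#' tracks. All generators are pure functions of the scenario and its seed:
#' the same scenario yields bit-identical output.
#'
#' Defaults emulate an eastern Sierra Nevada escarpment: winter range near
#' 1500--2000 m rising to summer range at 3000--4000 m, snowmelt and green-up
#' each delayed with elevation, green-up lagging snowmelt by 136 days on
#' average, a -6.5 degC/km temperature lapse, and sparse spring precipitation
#' events. Tracks are 12-h fixes simulated from a gamma/von Mises kernel with
#' softmax choice over proposal endpoints.
#'
#' @param seed integer seed governing all randomness derived from the
#'   scenario.
#' @param grid_size `c(rows, cols)` of the landscape grid.
#' @param cell_size cell edge (m).
#' @param elevation_range `c(min, max)` elevation (m); `min < max` unless the
#'   degenerate flat world `min == max` is requested.
#' @param ridge_amp relative amplitude of low-frequency ridges added to the
#'   monotone west--east gradient; `0` gives a pure linear gradient.
#' @param phenology list: `snowmelt_doy0` (calendar day-of-year of the FSC
#'   melt inflection at the lowest elevation), `snowmelt_slope` (days delay
#'   per metre), `greenup_lag` (days from snowmelt to green-up inflection),
#'   `senescence_lag` (days from green-up to senescence), `scalS_ndvi`,
#'   `scalA_ndvi`, `accum_snowday`, `accum_slope`, `scalS_fsc`, `scalA_fsc`
#'   (all days), `ndvi_lo`, `ndvi_hi0`, `ndvi_hi_slope` (raw-index bounds),
#'   `ndvi_noise_sd`, `fsc_noise_sd` (observation noise).
#' @param weather list: `lapse` (degC per m, negative), `tmax_mean`,
#'   `tmax_amp` (degC at the lowest elevation), `tmax_peak_doy`,
#'   `tmax_noise_sd` (daily region-wide anomaly), `precip_prob` (daily event
#'   probability) and `precip_mean` (mm, exponential event magnitude).
#' @param truth_betas named numeric vector of selection coefficients applied
#'   to simulated-track covariates (names must be covariate names understood
#'   by [sim_covariates()]).
#' @param kernel list: `shape`, `scale` (gamma step lengths, m), `mu`,
#'   `kappa` (von Mises turning angles, rad).
#' @param n_animals,n_steps animals and 12-h steps per animal to simulate.
#' @param step_interval_h hours between fixes.
#' @param n_proposals candidate endpoints per simulated step (>= 2);
#'   deliberately different from the analysis constant K = 30 so estimation
#'   never sees the generator's own choice set.
#' @param fix_drop_prob probability that any non-terminal fix is dropped,
#'   to exercise gap handling (default 0; collar fix-success rates are
#'   system-specific).
#' @return An object of class `migration_scenario` (a validated list).
#' @examples
#' sc <- migration_scenario(seed = 1, grid_size = c(40, 40))
#' dem <- make_landscape(sc)
#' @export
migration_scenario <- function(
    seed = 1L,
    grid_size = c(80L, 80L),
    cell_size = 100,
    elevation_range = c(1500, 4000),
    ridge_amp = 0.15,
    phenology = list(),
    weather = list(),
    truth_betas = c(elevation_z = -0.5, rel_ndvi = 1.0, log1p_dist_escape = -0.8),
    kernel = list(shape = 2, scale = 300, mu = 0, kappa = 0.5),
    n_animals = 30L,
    n_steps = 40L,
    step_interval_h = 12,
    n_proposals = 100L,
    fix_drop_prob = 0) {
  phen_default <- list(
    snowmelt_doy0 = 41, snowmelt_slope = 0.02,
    greenup_lag = 136, senescence_lag = 110,
    scalS_ndvi = 8, scalA_ndvi = 15,
    accum_snowday = 80, accum_slope = -0.01,
    scalS_fsc = 12, scalA_fsc = 8,
    ndvi_lo = 0.08, ndvi_hi0 = 0.75, ndvi_hi_slope = -8e-5,
    ndvi_noise_sd = 0.05, fsc_noise_sd = 5
  )
  weath_default <- list(
    lapse = -0.0065, tmax_mean = 22, tmax_amp = 14,
    tmax_peak_doy = 208, tmax_noise_sd = 2,
    precip_prob = 0.06, precip_mean = 8
  )
  phenology <- utils::modifyList(phen_default, phenology)
  weather <- utils::modifyList(weath_default, weather)

  stopifnot(length(grid_size) == 2, length(elevation_range) == 2)
  if (any(grid_size < 2)) {
    stop("grid_size must be at least 2 x 2", call. = FALSE)
  }
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("cell_size must be positive", call. = FALSE)
  }
  if (elevation_range[1] > elevation_range[2]) {
    stop("elevation_range must satisfy min <= max", call. = FALSE)
  }
  if (n_proposals < 2) {
    stop("n_proposals must be at least 2", call. = FALSE)
  }
  if (is.null(names(truth_betas)) && length(truth_betas) > 0) {
    stop("truth_betas must be a named vector", call. = FALSE)
  }
  stopifnot(
    kernel$shape > 0, kernel$scale > 0, kernel$kappa >= 0,
    n_animals >= 1, n_steps >= 1, step_interval_h > 0,
    fix_drop_prob >= 0, fix_drop_prob < 1
  )

  structure(
    list(
      seed = as.integer(seed),
      grid_size = as.integer(grid_size), cell_size = cell_size,
      elevation_range = elevation_range, ridge_amp = ridge_amp,
      phenology = phenology, weather = weather,
      truth_betas = truth_betas, kernel = kernel,
      n_animals = as.integer(n_animals), n_steps = as.integer(n_steps),
      step_interval_h = step_interval_h,
      n_proposals = as.integer(n_proposals),
      fix_drop_prob = fix_drop_prob
    ),
    class = "migration_scenario"
  )
}

#' @export
print.migration_scenario <- function(x, ...) {
  cat(sprintf(
    "<migration_scenario> seed %d, %d x %d cells @ %g m, elevation %g-%g m\n",
    x$seed, x$grid_size[1], x$grid_size[2], x$cell_size,
    x$elevation_range[1], x$elevation_range[2]
  ))
  cat(sprintf(
    "  %d animals x %d steps @ %g h; kernel gamma(%g, %g m), vM(kappa=%g)\n",
    x$n_animals, x$n_steps, x$step_interval_h,
    x$kernel$shape, x$kernel$scale, x$kernel$kappa
  ))
  if (length(x$truth_betas)) {
    cat(
      "  truth betas:",
      paste(names(x$truth_betas), sprintf("%+g", x$truth_betas),
        sep = "=", collapse = ", "
      ), "\n"
    )
  }
  invisible(x)
}

# deterministic child seed for a named generator stage
scenario_seed <- function(scenario, stage) {
  offs <- c(
    landscape = 11L, fields = 23L, tracks = 37L, profile = 53L,
    starts = 71L, classes = 89L
  )
  (scenario$seed * 1000L + offs[[stage]]) %% .Machine$integer.max
}

#' Generate the synthetic elevation model
#'
#' A smooth elevation field: a monotone west-to-east gradient plus seeded
#' low-frequency sinusoidal ridges, rescaled to span `elevation_range`
#' exactly. With `ridge_amp = 0` the field is a pure linear gradient, and a
#' degenerate `elevation_range` of zero width yields a constant grid.
#'
#' @param scenario a [migration_scenario()].
#' @return a [raster_grid()] of elevations (m).
#' @export
make_landscape <- function(scenario) {
  nr <- scenario$grid_size[1]
  nc <- scenario$grid_size[2]
  cs <- scenario$cell_size
  xs <- (seq_len(nc) - 0.5) * cs
  ys <- (seq_len(nr) - 0.5) * cs

  base <- matrix(rep((xs - xs[1]) / (xs[nc] - xs[1]), each = nr), nr, nc)

  if (scenario$ridge_amp > 0) {
    rng <- local({
      set.seed(scenario_seed(scenario, "landscape"))
      k <- 4L
      list(
        theta = stats::runif(k, 0, pi),
        freq = stats::runif(k, 2, 6) / (max(xs) - min(xs)),
        phase = stats::runif(k, 0, 2 * pi),
        amp = stats::runif(k, 0.3, 1)
      )
    })
    X <- matrix(rep(xs, each = nr), nr, nc)
    Y <- matrix(rep(ys, times = nc), nr, nc)
    ridge <- 0
    for (k in seq_along(rng$amp)) {
      u <- cos(rng$theta[k]) * X + sin(rng$theta[k]) * Y
      ridge <- ridge + rng$amp[k] * sin(2 * pi * rng$freq[k] * u + rng$phase[k])
    }
    ridge <- ridge / sum(rng$amp)
    g <- base + scenario$ridge_amp * ridge
    g <- (g - min(g)) / (max(g) - min(g))
  } else {
    g <- base
  }

  lo <- scenario$elevation_range[1]
  hi <- scenario$elevation_range[2]
  raster_grid(lo + (hi - lo) * g, xmin = 0, ymin = 0, cellsize = cs)
}

# true per-pixel phenology parameters implied by a scenario (calendar doy for
# NDVI; snow-year days for FSC)
true_phenology <- function(scenario, elevation) {
  p <- scenario$phenology
  e <- elevation$values
  de <- e - scenario$elevation_range[1]
  snowmelt_doy <- p$snowmelt_doy0 + p$snowmelt_slope * de
  list(
    xmidS_ndvi = snowmelt_doy + p$greenup_lag,
    xmidA_ndvi = snowmelt_doy + p$greenup_lag + p$senescence_lag,
    scalS_ndvi = p$scalS_ndvi, scalA_ndvi = p$scalA_ndvi,
    xmidS_fsc = p$accum_snowday + p$accum_slope * de,
    xmidA_fsc = doy_to_snowday(pmin(snowmelt_doy, 226)),
    scalS_fsc = p$scalS_fsc, scalA_fsc = p$scalA_fsc,
    ndvi_lo = p$ndvi_lo + 0 * e,
    ndvi_hi = p$ndvi_hi0 + p$ndvi_hi_slope * de
  )
}

#' Generate the dynamic environmental fields
#'
#' Builds the daily maximum-temperature, daily precipitation, daily
#' fractional-snow-cover and 16-day NDVI stacks implied by a scenario and its
#' elevation model. NDVI and FSC series are exact double-logistic curves in
#' time (plus optional Gaussian observation noise) whose inflection days
#' increase with pixel elevation; temperature follows the seasonal curve at
#' the lowest elevation shifted by the lapse rate, plus a region-wide daily
#' anomaly; precipitation is zero except on seeded event days (region-wide
#' exponential magnitudes).
#'
#' @param scenario a [migration_scenario()].
#' @param elevation the [make_landscape()] output for the same scenario.
#' @param noise if `FALSE`, observation noise on NDVI/FSC is suppressed
#'   (the curves are then exactly representable by the double-logistic
#'   model).
#' @return list with `tmax`, `precip`, `fsc` (daily; `fsc` on the snow-day
#'   axis), `ndvi` (16-day) [raster_stack()]s, and `truth` (per-pixel true
#'   phenology parameter matrices).
#' @export
make_dynamic_fields <- function(scenario, elevation, noise = TRUE) {
  p <- scenario$phenology
  w <- scenario$weather
  nr <- nrow(elevation$values)
  nc <- ncol(elevation$values)
  e <- elevation$values
  tr <- true_phenology(scenario, elevation)
  set.seed(scenario_seed(scenario, "fields"))

  days <- 1:365
  # temperature: seasonal curve at base elevation + lapse + daily anomaly
  seasonal <- w$tmax_mean + w$tmax_amp * cos(2 * pi * (days - w$tmax_peak_doy) / 365)
  anom <- if (noise) stats::rnorm(365, 0, w$tmax_noise_sd) else rep(0, 365)
  lapse_term <- w$lapse * (e - scenario$elevation_range[1])
  tmax <- array(0, c(nr, nc, 365))
  for (d in days) tmax[, , d] <- seasonal[d] + anom[d] + lapse_term

  # precipitation: sparse region-wide events
  ev <- stats::rbinom(365, 1, w$precip_prob) == 1
  mag <- ifelse(ev, stats::rexp(365, rate = 1 / w$precip_mean), 0)
  precip <- array(rep(mag, each = nr * nc), c(nr, nc, 365))

  # FSC: double logistic on the snow-day axis, percent scale
  sdays <- 1:365
  fsc <- array(0, c(nr, nc, 365))
  for (d in sdays) {
    v <- 100 * double_logistic_value(
      d, tr$xmidS_fsc, p$scalS_fsc, tr$xmidA_fsc, p$scalA_fsc
    )
    if (noise && p$fsc_noise_sd > 0) {
      v <- v + stats::rnorm(nr * nc, 0, p$fsc_noise_sd)
    }
    fsc[, , d] <- pmin(pmax(v, 0), 100)
  }

  # NDVI: 16-day composites on the calendar axis, raw index scale
  ndays <- seq(1, 365, by = 16)
  ndvi <- array(0, c(nr, nc, length(ndays)))
  for (i in seq_along(ndays)) {
    rel <- double_logistic_value(
      ndays[i], tr$xmidS_ndvi, p$scalS_ndvi, tr$xmidA_ndvi, p$scalA_ndvi
    )
    v <- tr$ndvi_lo + (tr$ndvi_hi - tr$ndvi_lo) * rel
    if (noise && p$ndvi_noise_sd > 0) {
      v <- v + stats::rnorm(nr * nc, 0, p$ndvi_noise_sd)
    }
    ndvi[, , i] <- pmin(pmax(v, -1), 1)
  }

  list(
    tmax = raster_stack(elevation, days, tmax, "doy"),
    precip = raster_stack(elevation, days, precip, "doy"),
    fsc = raster_stack(elevation, sdays, fsc, "snowday"),
    ndvi = raster_stack(elevation, ndays, ndvi, "doy"),
    truth = tr
  )
}
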