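#' Precompute the simulation world
#'
#' Bundles the closed-form covariate evaluators the track simulator selects
#' on: standardised elevation and slope (moments taken over the landscape),
#' cosine aspect, log distance to escape terrain, the true (generator-side)
#' phenology covariates, fractional snow cover, standardised daily maximum
#' temperature and log precipitation. Using the generator's own analytic
#' phenology here keeps simulation independent of the phenology *fitter*,
#' which is validated separately.
#'
#' @param scenario a [migration_scenario()].
#' @param elevation [make_landscape()] output.
#' @param fields [make_dynamic_fields()] output.
#' @return an object of class `sim_world` used by [simulate_issf_track()].
#' @export
prepare_sim_world <- function(scenario, elevation, fields) {
  terr <- terrain_covariates(elevation)
  tr <- fields$truth
  tmax_all <- fields$tmax$values
  structure(
    list(
      scenario = scenario,
      elevation = elevation,
      terrain = terr,
      fields = fields,
      truth = tr,
      elev_mean = mean(elevation$values), elev_sd = stats::sd(elevation$values),
      slope_mean = mean(terr$slope$values), slope_sd = stats::sd(terr$slope$values),
      tmax_mean = mean(tmax_all), tmax_sd = stats::sd(tmax_all)
    ),
    class = "sim_world"
  )
}

#' Evaluate simulation covariates at points
#'
#' @param world a [prepare_sim_world()] object.
#' @param x,y point coordinates (m); must lie on the grid.
#' @param doy calendar day-of-year (scalar or vector).
#' @param names covariate names to evaluate (any of `elevation_z`,
#'   `slope_z`, `cos_aspect`, `log1p_dist_escape`, `rel_ndvi`, `abs_ndvi`,
#'   `days_since_greenup`, `days_since_snowmelt`, `fsc`, `tmax_z`,
#'   `log1p_precip`).
#' @return a numeric matrix, one column per name.
#' @export
sim_covariates <- function(world, x, y, doy, names) {
  idx <- rg_cell_index(world$elevation, x, y)
  if (anyNA(idx)) stop("points must lie inside the landscape", call. = FALSE)
  n <- nrow(idx)
  doy <- rep_len(doy, n)
  tr <- world$truth
  pick <- function(m) if (is.matrix(m)) m[idx] else rep_len(m, n)
  out <- matrix(NA_real_, n, length(names), dimnames = list(NULL, names))
  for (nm in names) {
    out[, nm] <- switch(nm,
      elevation_z = (world$elevation$values[idx] - world$elev_mean) / world$elev_sd,
      slope_z = (world$terrain$slope$values[idx] - world$slope_mean) / world$slope_sd,
      cos_aspect = world$terrain$cos_aspect$values[idx],
      log1p_dist_escape = log1p(world$terrain$dist_escape$values[idx]),
      rel_ndvi = pmin(pmax(double_logistic_value(
        doy, pick(tr$xmidS_ndvi), tr$scalS_ndvi, pick(tr$xmidA_ndvi), tr$scalA_ndvi
      ), 0), 1),
      abs_ndvi = {
        rel <- pmin(pmax(double_logistic_value(
          doy, pick(tr$xmidS_ndvi), tr$scalS_ndvi, pick(tr$xmidA_ndvi), tr$scalA_ndvi
        ), 0), 1)
        pick(tr$ndvi_lo) + rel * (pick(tr$ndvi_hi) - pick(tr$ndvi_lo))
      },
      days_since_greenup = doy - pick(tr$xmidS_ndvi),
      days_since_snowmelt = doy - snowday_to_doy(pick(tr$xmidA_fsc)),
      fsc = rs_extract(world$fields$fsc, x, y, doy_to_snowday(doy)),
      tmax_z = (rs_extract(world$fields$tmax, x, y, doy) - world$tmax_mean) / world$tmax_sd,
      log1p_precip = log1p(rs_extract(world$fields$precip, x, y, doy)),
      stop("unknown simulation covariate: ", nm, call. = FALSE)
    )
  }
  out
}

#' Simulate one 12-h track from a known step-selection function
#'
#' At each step, `n_proposals` candidate endpoints are drawn from the
#' movement kernel (gamma length along the previous heading plus a von
#' Mises turn; the first step's heading is uniform on `[-pi, pi)`) and one
#' is selected with probability proportional to `exp(beta . x)`. Candidates
#' falling off the grid are redrawn (bounded retries). Fixes are returned at
#' exact `step_interval_h` spacing.
#'
#' @param scenario a [migration_scenario()].
#' @param world a [prepare_sim_world()] object.
#' @param beta named selection coefficients over [sim_covariates()] names
#'   (defaults to the scenario's `truth_betas`); `NULL` or an empty vector
#'   gives uniform choice among proposals.
#' @param start `c(x, y)` start point (m); must be on the grid.
#' @param animal_id identifier stored on the fixes.
#' @param t0_doy calendar day-of-year of the first fix.
#' @param seed integer seed.
#' @param beta_fun optional `function(doy)` returning the coefficient vector
#'   at a given day (time-varying selection, e.g. a migrant's rising
#'   elevation preference); overrides `beta`.
#' @param max_retry redraw rounds for off-grid proposals before erroring.
#' @param detail also record, per step, the index of the selected proposal
#'   and the number of proposals (for simulator diagnostics).
#' @return a tibble of fixes: `animal_id`, `timestamp` (UTC, nominal study
#'   year), `doy` (fractional), `x`, `y`. With `detail = TRUE`, a list
#'   `list(fixes, choices)` where `choices` has one row per step
#'   (`step`, `chosen`, `n_proposals`).
#' @export
simulate_issf_track <- function(scenario, world, beta = scenario$truth_betas,
                                start, animal_id = "a1", t0_doy = 100,
                                seed = 1L, beta_fun = NULL, max_retry = 50,
                                detail = FALSE) {
  if (!rg_inside(world$elevation, start[1], start[2])) {
    stop("start point off grid", call. = FALSE)
  }
  if (scenario$n_proposals < 2) {
    stop("n_proposals must be at least 2", call. = FALSE)
  }
  set.seed(seed)
  n_steps <- scenario$n_steps
  np <- scenario$n_proposals
  kern <- scenario$kernel
  dt_days <- scenario$step_interval_h / 24

  xs <- numeric(n_steps + 1)
  ys <- numeric(n_steps + 1)
  xs[1] <- start[1]
  ys[1] <- start[2]
  heading <- stats::runif(1, -pi, pi)
  chosen <- integer(n_steps)

  for (s in seq_len(n_steps)) {
    doy_s <- t0_doy + s * dt_days
    b <- if (!is.null(beta_fun)) beta_fun(doy_s) else beta
    sl <- stats::rgamma(np, shape = kern$shape, scale = kern$scale)
    ta <- rvonmises(np, mu = kern$mu, kappa = kern$kappa)
    hd <- heading + ta
    px <- xs[s] + sl * cos(hd)
    py <- ys[s] + sl * sin(hd)
    bad <- !rg_inside(world$elevation, px, py)
    tries <- 0L
    while (any(bad) && tries < max_retry) {
      nb <- sum(bad)
      sl[bad] <- stats::rgamma(nb, shape = kern$shape, scale = kern$scale)
      ta[bad] <- rvonmises(nb, mu = kern$mu, kappa = kern$kappa)
      hd <- heading + ta
      px[bad] <- xs[s] + sl[bad] * cos(hd[bad])
      py[bad] <- ys[s] + sl[bad] * sin(hd[bad])
      bad <- !rg_inside(world$elevation, px, py)
      tries <- tries + 1L
    }
    if (any(bad)) {
      stop("all proposals off grid after bounded retries at step ", s,
        call. = FALSE
      )
    }
    if (is.null(b) || length(b) == 0) {
      w <- rep(1, np)
    } else {
      xmat <- sim_covariates(world, px, py, doy_s, names(b))
      eta <- drop(xmat %*% b)
      w <- exp(eta - max(eta))
    }
    j <- sample.int(np, 1, prob = w)
    chosen[s] <- j
    xs[s + 1] <- px[j]
    ys[s + 1] <- py[j]
    heading <- atan2(ys[s + 1] - ys[s], xs[s + 1] - xs[s])
  }

  doy <- t0_doy + (0:n_steps) * dt_days
  ts0 <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC") - 86400
  fixes <- tibble::tibble(
    animal_id = animal_id,
    timestamp = ts0 + doy * 86400,
    doy = doy,
    x = xs, y = ys
  )
  if (scenario$fix_drop_prob > 0) {
    keep <- c(TRUE, stats::runif(n_steps - 1) >= scenario$fix_drop_prob, TRUE)
    fixes <- fixes[keep, ]
  }
  if (detail) {
    return(list(
      fixes = fixes,
      choices = tibble::tibble(
        step = seq_len(n_steps), chosen = chosen, n_proposals = np
      )
    ))
  }
  fixes
}

#' Simulate a population of tracks with known ground truth
#'
#' Draws each animal's class (resident / fast migrant / slow migrant), start
#' point in the low-elevation quarter of the landscape, and migration timing
#' `theta`, then simulates its track. Residents keep the scenario's base
#' selection coefficients throughout; migrants add a logistic ramp of
#' strength `migrant_elev_gain` to the elevation coefficient, centred on
#' their `theta` with timescale `phi` (fast: `phi_fast`; slow: `phi_slow`),
#' which produces a genuine uphill redistribution in the simulated fixes.
#'
#' @param scenario a [migration_scenario()].
#' @param world a [prepare_sim_world()] object.
#' @param class_probs probabilities for resident / fast / slow classes.
#' @param theta_range uniform range for migrants' midpoint day.
#' @param phi_fast,phi_slow migration timescales (days).
#' @param migrant_elev_gain added elevation coefficient after the ramp.
#' @param t0_doy first-fix day-of-year.
#' @param seed integer seed.
#' @return list with `fixes` (all animals) and `truth` (one row per animal:
#'   `animal_id`, `class`, `theta`, `phi`, plus the base coefficients).
#' @export
simulate_population <- function(scenario, world,
                                class_probs = c(resident = 0.4, fast = 0.3, slow = 0.3),
                                theta_range = c(120, 170),
                                phi_fast = 0.7, phi_slow = 4,
                                migrant_elev_gain = 3,
                                t0_doy = 100, seed = scenario$seed) {
  set.seed(seed)
  n <- scenario$n_animals
  cls <- sample(names(class_probs), n, replace = TRUE, prob = class_probs)
  theta <- stats::runif(n, theta_range[1], theta_range[2])
  phi <- ifelse(cls == "fast", phi_fast, phi_slow)
  ext <- rg_extent(world$elevation)
  # start in the low-elevation (western) quarter
  sx <- stats::runif(n, ext["xmin"] + 0.02 * diff(ext[1:2]), ext["xmin"] + 0.25 * diff(ext[1:2]))
  sy <- stats::runif(n, ext["ymin"] + 0.05 * diff(ext[3:4]), ext["ymax"] - 0.05 * diff(ext[3:4]))
  seeds <- sample.int(.Machine$integer.max %/% 2, n)

  base_beta <- scenario$truth_betas
  fixes <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("animal%02d", i)
    bf <- if (cls[i] == "resident") {
      NULL
    } else {
      local({
        th <- theta[i]
        ph <- phi[i]
        function(doy) {
          b <- base_beta
          ramp <- migrant_elev_gain / (1 + exp((th - doy) / ph))
          b["elevation_z"] <- (if ("elevation_z" %in% names(b)) b[["elevation_z"]] else 0) + ramp
          b
        }
      })
    }
    fixes[[i]] <- simulate_issf_track(
      scenario, world,
      beta = base_beta, start = c(sx[i], sy[i]),
      animal_id = id, t0_doy = t0_doy, seed = seeds[i], beta_fun = bf
    )
  }
  truth <- tibble::tibble(
    animal_id = sprintf("animal%02d", seq_len(n)),
    class = ifelse(cls == "resident", "resident", "migrant"),
    tactic = cls,
    theta = ifelse(cls == "resident", NA_real_, theta),
    phi = ifelse(cls == "resident", NA_real_, phi)
  )
  list(fixes = dplyr::bind_rows(fixes), truth = truth)
}

#' Simulate a daily elevation-use profile
#'
#' Ground-truth profiles for the migration classifier: residents hold a
#' constant elevation plus noise; migrants rise by `delta` metres through a
#' logistic centred on day `theta` with timescale `phi` days and (optionally)
#' descend again in autumn through a mirrored logistic at `theta2`.
#' At `theta` the noiseless migrant profile sits exactly `delta / 2` above
#' its baseline.
#'
#' @param class `"resident"` or `"migrant"`.
#' @param delta displacement height (m, >= 0).
#' @param theta migration midpoint (day-of-year).
#' @param phi migration timescale (days, > 0).
#' @param noise_sd daily elevation noise (m).
#' @param days day-of-year vector for the series.
#' @param elev0 baseline elevation (m).
#' @param descend include the autumn return.
#' @param theta2,phi2 return midpoint and timescale (migrants with
#'   `descend = TRUE`).
#' @param seed integer seed.
#' @return a tibble with `day` and `elevation`.
#' @export
simulate_elevation_profile <- function(class = c("resident", "migrant"),
                                       delta = 1000, theta = 150, phi = 5,
                                       noise_sd = 50, days = 1:365,
                                       elev0 = 1800, descend = TRUE,
                                       theta2 = theta + 120, phi2 = phi,
                                       seed = 1L) {
  class <- match.arg(class)
  if (phi <= 0) stop("`phi` must be positive", call. = FALSE)
  if (delta < 0) stop("`delta` must be non-negative", call. = FALSE)
  set.seed(seed)
  mu <- if (class == "resident") {
    rep(elev0, length(days))
  } else {
    up <- delta / (1 + exp((theta - days) / phi))
    down <- if (descend) delta / (1 + exp((theta2 - days) / phi2)) else 0
    elev0 + up - down
  }
  tibble::tibble(
    day = days,
    elevation = mu + stats::rnorm(length(days), 0, noise_sd)
  )
}
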