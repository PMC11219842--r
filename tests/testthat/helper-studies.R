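# Reusable simulation studies backing the acceptance-style checks.
# Each is a pure function of its seeds so tests stay reproducible.

# iSSA parameter recovery: simulate tracks under known selection, rebuild
# strata with the fitted kernel, fit with movement-adjustment terms, and
# record per-coefficient CI coverage and bias.
recovery_study <- function(n_reps, world_seed = 42, base_seed = 1000,
                           n_animals = 30, n_steps = 40) {
  covs <- c("elevation_z", "rel_ndvi", "log1p_dist_escape")
  truth <- c(elevation_z = -0.5, rel_ndvi = 1.0, log1p_dist_escape = -0.8)
  sc <- migration_scenario(
    seed = world_seed, grid_size = c(50, 50), cell_size = 200,
    n_animals = n_animals, n_steps = n_steps, truth_betas = truth
  )
  dem <- make_landscape(sc)
  fields <- make_dynamic_fields(sc, dem)
  world <- prepare_sim_world(sc, dem, fields)
  ext <- rg_extent(dem)

  one_rep <- function(r) {
    set.seed(base_seed + r)
    sx <- stats::runif(n_animals, 2000, 0.5 * ext[["xmax"]])
    sy <- stats::runif(n_animals, 2000, ext[["ymax"]] - 2000)
    seeds <- sample.int(2^30, n_animals)
    fx <- dplyr::bind_rows(lapply(seq_len(n_animals), function(i) {
      simulate_issf_track(sc, world,
        start = c(sx[i], sy[i]),
        animal_id = sprintf("a%02d", i), t0_doy = 200, seed = seeds[i]
      )
    }))
    st <- build_steps(rarify_track(fx))
    kern <- fit_movement_kernel(st)
    stra <- suppressMessages(
      sample_available(st, kern, k = 30, extent = dem, seed = base_seed * 2 + r)
    )
    X <- sim_covariates(world, stra$x, stra$y, stra$doy, covs)
    d <- dplyr::bind_cols(stra, tibble::as_tibble(X))
    d$log_sl <- log(pmax(d$sl, 1e-6))
    d$cos_ta <- cos(d$ta)
    fit <- fit_clogit(d, c(covs, "sl", "log_sl", "cos_ta"))
    est <- fit$beta[covs]
    se <- fit$se_robust[covs]
    # CR1 robust intervals use t critical values with G - 1 df
    q <- stats::qt(0.975, fit$n_individuals - 1)
    list(
      est = est,
      cover = truth >= est - q * se & truth <= est + q * se,
      converged = fit$converged
    )
  }
  reps <- lapply(seq_len(n_reps), one_rep)
  est <- do.call(rbind, lapply(reps, `[[`, "est"))
  cover <- do.call(rbind, lapply(reps, `[[`, "cover"))
  list(
    truth = truth,
    coverage = colMeans(cover),
    bias = colMeans(est) - truth,
    mean_abs_bias = mean(abs(colMeans(est) - truth)),
    all_converged = all(vapply(reps, `[[`, logical(1), "converged"))
  )
}

# phenology recovery: noisy double-logistic series over a realistic spread
# of inflection days; returns the hit rates for green-up (NDVI, 16-day) and
# snowmelt (FSC, daily) timing.
phenology_study <- function(n_pixels = 500, seed = 7,
                            ndvi_noise = 0.05, fsc_noise = 5) {
  set.seed(seed)
  elev <- stats::runif(n_pixels, 1500, 4000)
  xmidS <- 41 + 0.02 * (elev - 1500) + 136 # green-up day
  xmidA <- xmidS + 110
  melt_sday <- doy_to_snowday(41 + 0.02 * (elev - 1500))
  ts16 <- seq(1, 365, by = 16)

  # the fitter's contract takes a rescaled [0, 1] series; noise applies on
  # that scale (the percentile-rescale step's own distortion is characterised
  # separately in the vignette)
  greenup_err <- vapply(seq_len(n_pixels), function(i) {
    rel <- double_logistic_value(ts16, xmidS[i], 8, xmidA[i], 15) +
      stats::rnorm(length(ts16), 0, ndvi_noise)
    f <- fit_double_logistic(ts16, pmin(pmax(rel, 0), 1), "ndvi")
    if (!f$converged) {
      return(NA_real_)
    }
    f$xmidS - xmidS[i]
  }, numeric(1))

  tsd <- 1:365
  snowmelt_err <- vapply(seq_len(n_pixels), function(i) {
    raw <- 100 * double_logistic_value(tsd, 80, 12, melt_sday[i], 8) +
      stats::rnorm(365, 0, fsc_noise)
    f <- fit_double_logistic(tsd, pmin(pmax(raw, 0), 100), "fsc")
    if (!f$converged) {
      return(NA_real_)
    }
    f$xmidA - melt_sday[i]
  }, numeric(1))

  list(
    greenup_hit = mean(abs(greenup_err) <= 3, na.rm = FALSE),
    snowmelt_hit = mean(abs(snowmelt_err) <= 1, na.rm = FALSE),
    greenup_err = greenup_err, snowmelt_err = snowmelt_err
  )
}

# migration classification: 100 synthetic animal-years with known classes
migration_study <- function(n_migrants = 50, n_residents = 50, seed = 17,
                            noise_sd = 50) {
  set.seed(seed)
  delta <- stats::runif(n_migrants, 600, 1500)
  theta <- stats::runif(n_migrants, 120, 180)
  phi <- stats::runif(n_migrants, 0.5, 6)
  seeds <- sample.int(2^30, n_migrants + n_residents)

  rows <- vector("list", n_migrants + n_residents)
  for (i in seq_len(n_migrants)) {
    pr <- simulate_elevation_profile("migrant",
      delta = delta[i], theta = theta[i],
      phi = phi[i], noise_sd = noise_sd, seed = seeds[i]
    )
    fits <- fit_elevation_models(pr$day, pr$elevation)
    rec <- classify_strategy(fits, pr$day)
    rows[[i]] <- tibble::tibble(
      true_class = "migrant", true_theta = theta[i], true_phi = phi[i],
      class = rec$class, theta = rec$theta, phi = rec$phi
    )
  }
  for (j in seq_len(n_residents)) {
    pr <- simulate_elevation_profile("resident",
      noise_sd = noise_sd,
      seed = seeds[n_migrants + j]
    )
    fits <- fit_elevation_models(pr$day, pr$elevation)
    rec <- classify_strategy(fits, pr$day)
    rows[[n_migrants + j]] <- tibble::tibble(
      true_class = "resident", true_theta = NA_real_, true_phi = NA_real_,
      class = rec$class, theta = rec$theta, phi = rec$phi
    )
  }
  res <- dplyr::bind_rows(rows)
  ok_mig <- res$true_class == "migrant" & res$class == "migrant"
  list(
    results = res,
    accuracy = mean(res$class == res$true_class),
    theta_bias = mean(res$theta[ok_mig] - res$true_theta[ok_mig])
  )
}

# LMM recovery: green-up-vs-snowmelt herd data with slope 0.77
lmm_study <- function(n_reps = 200, seed = 29) {
  set.seed(seed)
  hits <- vapply(seq_len(n_reps), function(r) {
    d <- data.frame(
      snowmelt = stats::rnorm(280, 60, 10),
      herd = factor(rep(1:14, each = 20))
    )
    d$greenup <- 130 + 0.77 * d$snowmelt + stats::rnorm(14, 0, 5)[d$herd] +
      stats::rnorm(280, 0, 3)
    fit <- fit_lmm(d, "greenup", "snowmelt", "herd")
    sl <- fit$fixed[fit$fixed$term == "snowmelt", ]
    abs(sl$estimate - 0.77) <= 2 * sl$std.error
  }, logical(1))
  mean(hits)
}

# null-calibration: beta = 0 strata from the track pipeline
null_strata <- function(seed = 3, n_animals = 15, n_steps = 40) {
  sc <- migration_scenario(
    seed = seed, grid_size = c(50, 50), cell_size = 200,
    n_animals = n_animals, n_steps = n_steps
  )
  dem <- make_landscape(sc)
  fields <- make_dynamic_fields(sc, dem)
  world <- prepare_sim_world(sc, dem, fields)
  ext <- rg_extent(dem)
  set.seed(seed + 1)
  sx <- stats::runif(n_animals, 2000, ext[["xmax"]] - 2000)
  sy <- stats::runif(n_animals, 2000, ext[["ymax"]] - 2000)
  seeds <- sample.int(2^30, n_animals)
  fx <- dplyr::bind_rows(lapply(seq_len(n_animals), function(i) {
    simulate_issf_track(sc, world,
      beta = NULL, start = c(sx[i], sy[i]),
      animal_id = sprintf("a%02d", i), t0_doy = 200, seed = seeds[i]
    )
  }))
  st <- build_steps(rarify_track(fx))
  kern <- fit_movement_kernel(st)
  stra <- suppressMessages(
    sample_available(st, kern, k = 30, extent = dem, seed = seed + 2)
  )
  covs <- c("elevation_z", "rel_ndvi", "log1p_dist_escape")
  X <- sim_covariates(world, stra$x, stra$y, stra$doy, covs)
  d <- dplyr::bind_cols(stra, tibble::as_tibble(X))
  list(data = d, covariates = covs)
}

# within-stratum case-label permutation followed by a refit
permute_refit <- function(data, covariates, seed) {
  set.seed(seed)
  d <- data
  idx <- split(seq_len(nrow(d)), d$stratum_id)
  for (ii in idx) d$case[ii] <- sample(d$case[ii])
  fit_clogit(d, covariates)
}
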