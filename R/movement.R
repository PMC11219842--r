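#' Temporally rarify a GPS track to a fixed interval
#'
#' Greedy slot filling: starting at each animal's first fix, one fix is kept
#' per `interval_h` slot -- the fix nearest the slot time within
#' `+-tolerance_h`. Slots with no candidate stay empty (a gap); downstream,
#' no step is formed across a gap. Already-rarefied data pass through
#' unchanged (the operation is idempotent).
#'
#' @param fixes data frame with `animal_id`, `timestamp` (POSIXct) and
#'   coordinate columns; extra columns are preserved.
#' @param interval_h target interval (hours).
#' @param tolerance_h half-width of the acceptance window around each slot
#'   (hours).
#' @return a tibble of kept fixes with an added integer `slot` column.
#' @export
rarify_track <- function(fixes, interval_h = 12, tolerance_h = 2) {
  if (nrow(fixes) == 0) {
    return(dplyr::mutate(tibble::as_tibble(fixes), slot = integer(0)))
  }
  stopifnot(all(c("animal_id", "timestamp") %in% names(fixes)))
  fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::arrange(.data$timestamp, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      t0 <- df$timestamp[1]
      hrs <- as.numeric(difftime(df$timestamp, t0, units = "hours"))
      if (is.unsorted(hrs, strictly = TRUE)) {
        stop("timestamps must be strictly increasing within an animal",
          call. = FALSE
        )
      }
      slot <- round(hrs / interval_h)
      off <- abs(hrs - slot * interval_h)
      keep <- df[off <= tolerance_h, , drop = FALSE]
      keep$slot <- slot[off <= tolerance_h]
      keep$off <- off[off <= tolerance_h]
      keep <- keep |>
        dplyr::group_by(.data$slot) |>
        dplyr::slice_min(.data$off, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      keep$off <- NULL
      keep
    }) |>
    dplyr::ungroup()
}

#' Build used steps from rarefied fixes
#'
#' Consecutive kept slots form a step: Euclidean length, absolute heading,
#' and the signed turning angle (change in heading, in `(-pi, pi]`,
#' positive = left turn). A step requires its start and end slots to be
#' adjacent (no gap). Turning angles need three consecutive fixes, so the
#' first step of each burst has an undefined (NA) turn angle.
#'
#' @param fixes rarefied fixes from [rarify_track()] (columns `animal_id`,
#'   `timestamp`, `x`, `y`, `slot`).
#' @return a tibble of steps: `animal_id`, `t_start`, `t_end`, `x1`, `y1`,
#'   `x2`, `y2`, `length`, `heading`, `turn_angle`, `step_id`.
#' @export
build_steps <- function(fixes) {
  stopifnot(all(c("animal_id", "timestamp", "x", "y", "slot") %in% names(fixes)))
  steps <- fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::arrange(.data$slot, .by_group = TRUE) |>
    dplyr::mutate(
      x2 = dplyr::lead(.data$x), y2 = dplyr::lead(.data$y),
      t_end = dplyr::lead(.data$timestamp),
      gap = dplyr::lead(.data$slot) - .data$slot
    ) |>
    dplyr::filter(!is.na(.data$gap) & .data$gap == 1) |>
    dplyr::mutate(
      length = sqrt((.data$x2 - .data$x)^2 + (.data$y2 - .data$y)^2),
      heading = atan2(.data$y2 - .data$y, .data$x2 - .data$x),
      prev_slot_end = dplyr::lag(.data$slot) + 1L,
      prev_heading = dplyr::lag(.data$heading),
      contiguous = !is.na(.data$prev_slot_end) & .data$prev_slot_end == .data$slot,
      turn_angle = ifelse(.data$contiguous,
        wrap_angle(.data$heading - .data$prev_heading), NA_real_
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::rename(x1 = "x", y1 = "y", t_start = "timestamp")
  steps$step_id <- seq_len(nrow(steps))
  steps |>
    dplyr::select(dplyr::any_of(c(
      "step_id", "animal_id", "t_start", "t_end", "slot", "doy",
      "x1", "y1", "x2", "y2", "length", "heading", "prev_heading",
      "turn_angle", "herd_unit", "sex", "year"
    )))
}

#' Fit the population movement kernel
#'
#' Gamma step lengths by maximum likelihood (Newton on the digamma
#' equation; zero lengths are replaced by half the minimum positive length
#' before fitting) and von Mises turning angles by maximum likelihood
#' (circular mean; concentration by `A(kappa)` inversion, capped at
#' `kappa_max`).
#'
#' @param steps step table from [build_steps()] (uses `length` and
#'   `turn_angle`; steps with undefined angles contribute to the gamma fit
#'   only).
#' @param min_steps minimum number of steps with defined turning angles.
#' @param kappa_max concentration cap for degenerate angle samples.
#' @return an object of class `movement_kernel`: list with `gamma_shape`,
#'   `gamma_scale` (m), `vm_mu` (rad), `vm_kappa`, `n_lengths`, `n_angles`.
#' @export
fit_movement_kernel <- function(steps, min_steps = 30, kappa_max = 500) {
  len <- steps$length[is.finite(steps$length)]
  ang <- steps$turn_angle[is.finite(steps$turn_angle)]
  if (length(ang) < min_steps) {
    stop("need at least ", min_steps, " steps with defined turning angles",
      call. = FALSE
    )
  }
  if (all(len == 0)) stop("all step lengths are zero", call. = FALSE)
  pos_min <- min(len[len > 0])
  len[len == 0] <- pos_min / 2
  gf <- fit_gamma(len)
  vf <- fit_vonmises(ang, kappa_max = kappa_max)
  structure(
    list(
      gamma_shape = gf$shape, gamma_scale = gf$scale,
      vm_mu = vf$mu, vm_kappa = vf$kappa,
      n_lengths = length(len), n_angles = length(ang)
    ),
    class = "movement_kernel"
  )
}

#' @export
print.movement_kernel <- function(x, ...) {
  cat(sprintf(
    "<movement_kernel> gamma(shape %.3f, scale %.1f m), von Mises(mu %.3f, kappa %.3f)\n",
    x$gamma_shape, x$gamma_scale, x$vm_mu, x$vm_kappa
  ))
  invisible(x)
}

#' @export
tidy.movement_kernel <- function(x, ...) {
  tibble::tibble(
    term = c("gamma_shape", "gamma_scale", "vm_mu", "vm_kappa"),
    estimate = c(x$gamma_shape, x$gamma_scale, x$vm_mu, x$vm_kappa)
  )
}

#' Sample available steps for each used step
#'
#' Pairs every eligible used step (one with a defined previous heading) with
#' `k` available endpoints drawn from the movement kernel: a gamma length
#' along the previous heading rotated by a von Mises turn. Endpoints falling
#' off the raster are redrawn up to `max_retry` times; strata that still
#' contain off-grid endpoints are dropped whole, keeping choice sets
#' balanced.
#'
#' @param steps step table from [build_steps()].
#' @param kernel a [fit_movement_kernel()] result (or compatible list).
#' @param k available endpoints per stratum (default 30, giving 31 rows per
#'   stratum including the used step).
#' @param extent a [raster_grid()] whose extent bounds valid endpoints, or
#'   `NULL` for an unbounded plane.
#' @param max_retry redraw attempts for off-grid endpoints.
#' @param seed integer seed for the draws.
#' @return a long tibble: `stratum_id`, `animal_id`, `t_start`, `t_end`,
#'   `x1`, `y1` (shared start), `x`, `y` (endpoint), `case` (1 used, 0
#'   available), `sl` (step length), `ta` (turn angle) plus any carried
#'   grouping columns. Attribute `dropped_strata` counts strata discarded
#'   after retry exhaustion.
#' @export
sample_available <- function(steps, kernel, k = 30, extent = NULL,
                             max_retry = 10, seed = 1L) {
  eligible <- steps |>
    dplyr::filter(is.finite(.data$turn_angle))
  if (nrow(eligible) == 0) {
    stop("no steps with defined previous heading", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(eligible)
  carry <- intersect(
    c("animal_id", "t_start", "t_end", "doy", "herd_unit", "sex", "year", "slot"),
    names(eligible)
  )

  # draw all k x n available steps at once; retries operate on the flat vector
  m <- n * k
  strat_of <- rep(seq_len(n), each = k)
  sl <- stats::rgamma(m, shape = kernel$gamma_shape, scale = kernel$gamma_scale)
  ta <- rvonmises(m, mu = kernel$vm_mu, kappa = kernel$vm_kappa)
  hd <- eligible$prev_heading[strat_of] + ta
  ax <- eligible$x1[strat_of] + sl * cos(hd)
  ay <- eligible$y1[strat_of] + sl * sin(hd)
  drop_stratum <- rep(FALSE, n)
  if (!is.null(extent)) {
    bad <- !rg_inside(extent, ax, ay)
    tries <- 0L
    while (any(bad) && tries < max_retry) {
      nb <- sum(bad)
      sl[bad] <- stats::rgamma(nb, shape = kernel$gamma_shape, scale = kernel$gamma_scale)
      ta[bad] <- rvonmises(nb, mu = kernel$vm_mu, kappa = kernel$vm_kappa)
      hd_b <- eligible$prev_heading[strat_of[bad]] + ta[bad]
      ax[bad] <- eligible$x1[strat_of[bad]] + sl[bad] * cos(hd_b)
      ay[bad] <- eligible$y1[strat_of[bad]] + sl[bad] * sin(hd_b)
      bad <- !rg_inside(extent, ax, ay)
      tries <- tries + 1L
    }
    if (any(bad)) drop_stratum[unique(strat_of[bad])] <- TRUE
  }

  # interleave: used row then its k available rows, per stratum
  row_stratum <- rep(seq_len(n), each = k + 1)
  is_used <- rep(c(TRUE, rep(FALSE, k)), times = n)
  avail_at <- which(!is_used)
  res <- eligible[row_stratum, carry, drop = FALSE]
  res$stratum_id <- eligible$step_id[row_stratum]
  res$x1 <- eligible$x1[row_stratum]
  res$y1 <- eligible$y1[row_stratum]
  res$case <- as.integer(is_used)
  res$x <- NA_real_
  res$y <- NA_real_
  res$sl <- NA_real_
  res$ta <- NA_real_
  res$x[is_used] <- eligible$x2
  res$y[is_used] <- eligible$y2
  res$sl[is_used] <- eligible$length
  res$ta[is_used] <- eligible$turn_angle
  res$x[avail_at] <- ax
  res$y[avail_at] <- ay
  res$sl[avail_at] <- sl
  res$ta[avail_at] <- ta
  res <- tibble::as_tibble(res)

  dropped <- sum(drop_stratum)
  if (dropped > 0) {
    res <- res[!drop_stratum[row_stratum], , drop = FALSE]
    message(dropped, " strata dropped after off-grid retry exhaustion")
  }
  attr(res, "dropped_strata") <- dropped
  res
}

#' Extract environmental covariates at step endpoints
#'
#' Nearest-cell extraction at each product's native grid. Terrain layers are
#' static; snowmelt and green-up timing are fixed within a year (they come
#' from the annual phenology fits); FSC, distance from snow, NDVI metrics
#' and daily weather vary by day. Also records the startpoint temperature
#' and precipitation needed for the hot-day / raining statuses. Rows with
#' any missing covariate mark their whole stratum for dropping (done in
#' [transform_covariates()]), keeping choice sets balanced.
#'
#' @param strata long table from [sample_available()], with a `doy` column
#'   (calendar day-of-year of the step start) or `t_start` as POSIXct from
#'   which `doy` is derived.
#' @param terrain list from [terrain_covariates()].
#' @param fields list with `tmax`, `precip` (daily, doy axis), `fsc`
#'   (daily, snow-day axis), `ndvi` (unused here; phenology enters through
#'   the fits) as [raster_stack()]s.
#' @param pheno_rasters list of [raster_grid()]s of per-pixel phenology-fit
#'   parameters: `greenup_doy`, `scalS`, `xmidA_ndvi`, `scalA`, `lo`, `hi`
#'   (NDVI fit, calendar axis) and `snowmelt_doy` (FSC fit already converted
#'   to the calendar axis).
#' @param snow_threshold FSC percent defining "snow" for the
#'   distance-to-snow covariate.
#' @return the input tibble with raw covariate columns appended.
#' @export
extract_covariates <- function(strata, terrain, fields, pheno_rasters,
                               snow_threshold = 50) {
  stopifnot(nrow(strata) > 0)
  if (!"doy" %in% names(strata)) {
    strata$doy <- as.integer(strftime(strata$t_start, "%j"))
  }
  x <- strata$x
  y <- strata$y

  strata$elevation <- rg_extract(terrain$elevation, x, y)
  strata$slope <- rg_extract(terrain$slope, x, y)
  strata$cos_aspect <- rg_extract(terrain$cos_aspect, x, y)
  strata$dist_escape <- rg_extract(terrain$dist_escape, x, y)

  # annual phenology-derived layers (fixed within a year)
  greenup <- rg_extract(pheno_rasters$greenup_doy, x, y)
  snowmelt <- rg_extract(pheno_rasters$snowmelt_doy, x, y)
  scalS <- rg_extract(pheno_rasters$scalS, x, y)
  xmidA_n <- rg_extract(pheno_rasters$xmidA_ndvi, x, y)
  scalA <- rg_extract(pheno_rasters$scalA, x, y)
  lo <- rg_extract(pheno_rasters$lo, x, y)
  hi <- rg_extract(pheno_rasters$hi, x, y)
  rel <- pmin(pmax(
    double_logistic_value(strata$doy, greenup, scalS, xmidA_n, scalA), 0
  ), 1)
  strata$rel_ndvi <- rel
  strata$abs_ndvi <- lo + rel * (hi - lo)
  strata$days_since_greenup <- strata$doy - greenup
  strata$days_since_snowmelt <- strata$doy - snowmelt

  # daily layers
  sdoy <- doy_to_snowday(strata$doy)
  strata$fsc <- rs_extract(fields$fsc, x, y, sdoy)
  strata$tmax <- rs_extract(fields$tmax, x, y, strata$doy)
  strata$precip <- rs_extract(fields$precip, x, y, strata$doy)
  strata$tmax_start <- rs_extract(fields$tmax, strata$x1, strata$y1, strata$doy)
  strata$precip_start <- rs_extract(fields$precip, strata$x1, strata$y1, strata$doy)

  # distance to dense snowpack, per unique day
  strata$dist_snow <- NA_real_
  for (d in unique(sdoy)) {
    dmap <- suppressWarnings(distance_to_snow(fields$fsc, d, snow_threshold))
    sel <- sdoy == d
    strata$dist_snow[sel] <- rg_extract(dmap, x[sel], y[sel])
  }
  strata$dist_snow[is.infinite(strata$dist_snow)] <- NA_real_
  strata
}

#' Transform raw covariates into the model design
#'
#' Applies the standard covariate transforms: z-scores for elevation, slope
#' and temperature (pooled over used and available rows of the full
#' design), natural `log(value + 1)` for precipitation and the two
#' distances, the hot-day indicator (startpoint temperature above the 75th
#' percentile of that animal-year's startpoint temperatures,
#' linear-interpolation quantile), the raining indicator (startpoint
#' precipitation > 0 mm), and the elevation-by-status interactions formed
#' after z-scoring. Strata containing any missing covariate are dropped
#' whole.
#'
#' @param strata raw covariate table from [extract_covariates()].
#' @param year_col optional column name giving the year of each stratum for
#'   the animal-year hot-day threshold; if absent all of an animal's strata
#'   form one "year".
#' @return a tibble with the model columns `elevation_z`, `slope_z`,
#'   `cos_aspect`, `log1p_dist_escape`, `tmax_z`, `log1p_precip`, `fsc`,
#'   `log1p_dist_snow`, `days_since_snowmelt`, `abs_ndvi`, `rel_ndvi`,
#'   `days_since_greenup`, `hot_start`, `rain_start`, `elev_x_hot`,
#'   `elev_x_rain`, plus ids. Attribute `n_dropped_strata` records the
#'   balanced drops.
#' @export
transform_covariates <- function(strata, year_col = NULL) {
  raw_cov <- c(
    "elevation", "slope", "cos_aspect", "dist_escape", "tmax", "precip",
    "fsc", "dist_snow", "days_since_snowmelt", "abs_ndvi", "rel_ndvi",
    "days_since_greenup", "tmax_start", "precip_start"
  )
  present <- intersect(raw_cov, names(strata))
  incomplete <- !stats::complete.cases(strata[, present, drop = FALSE])
  bad_strata <- unique(strata$stratum_id[incomplete])
  out <- strata |>
    dplyr::filter(!(.data$stratum_id %in% bad_strata))
  attr_drop <- length(bad_strata)
  if (nrow(out) == 0) stop("all strata dropped as incomplete", call. = FALSE)

  zscore <- function(v, label) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("zero variance in z-scored column ", label, call. = FALSE)
    }
    (v - mean(v)) / s
  }
  out$elevation_z <- zscore(out$elevation, "elevation")
  out$slope_z <- zscore(out$slope, "slope")
  out$tmax_z <- zscore(out$tmax, "tmax")
  out$log1p_dist_escape <- log1p(out$dist_escape)
  out$log1p_precip <- log1p(out$precip)
  out$log1p_dist_snow <- log1p(out$dist_snow)

  # hot-day threshold per animal-year from startpoint temperatures of
  # retained strata (one startpoint value per stratum)
  if (is.null(year_col) || !year_col %in% names(out)) {
    out$.ay <- as.character(out$animal_id)
  } else {
    out$.ay <- paste(out$animal_id, out[[year_col]], sep = "_")
  }
  thr <- out |>
    dplyr::distinct(.data$.ay, .data$stratum_id, .data$tmax_start) |>
    dplyr::group_by(.data$.ay) |>
    dplyr::summarise(hot_thr = vm_quantile(.data$tmax_start, 0.75))
  out <- dplyr::left_join(out, thr, by = ".ay")
  out$hot_start <- as.integer(out$tmax_start > out$hot_thr)
  out$rain_start <- as.integer(out$precip_start > 0)
  out$elev_x_hot <- out$elevation_z * out$hot_start
  out$elev_x_rain <- out$elevation_z * out$rain_start
  out$.ay <- NULL
  out$hot_thr <- NULL
  attr(out, "n_dropped_strata") <- attr_drop
  out
}

#' Equalise observations across individuals
#'
#' Randomly subsamples every individual's strata down to the minimum
#' per-individual stratum count, so each animal contributes equally to the
#' population-level fit.
#'
#' @param strata long stratum table with `animal_id` and `stratum_id`.
#' @param seed integer seed for the subsample.
#' @return the subsampled tibble.
#' @export
balance_individuals <- function(strata, seed = 1L) {
  set.seed(seed)
  per <- strata |>
    dplyr::distinct(.data$animal_id, .data$stratum_id) |>
    dplyr::count(.data$animal_id)
  m <- min(per$n)
  keep <- strata |>
    dplyr::distinct(.data$animal_id, .data$stratum_id) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::slice_sample(n = m) |>
    dplyr::ungroup()
  dplyr::semi_join(strata, keep, by = c("animal_id", "stratum_id"))
}
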