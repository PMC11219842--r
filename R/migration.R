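#' Fit the candidate elevational displacement models
#'
#' The elevational analogue of net-squared-displacement migration models.
#' Three candidate mean structures are fit to a daily elevation series by
#' nonlinear least squares and compared by AIC (Gaussian residuals):
#' * resident: `elev(t) = gamma0` (constant position through time);
#' * disperser: `gamma0 + delta / (1 + exp((theta - t)/phi))` (a single
#'   displacement);
#' * migrant: the disperser curve minus a second logistic
#'   `delta / (1 + exp((theta2 - t)/phi2))` (an up-and-down
#'   redistribution), with `theta2 > theta`.
#'
#' Unconverged candidates are excluded from the comparison. Disperser and
#' migrant fits use a grid of starting midpoints to avoid local optima.
#'
#' @param day day ordinals (need >= 60 days spanning the season).
#' @param elevation daily elevations (m); same length as `day`.
#' @return a list of `nsd_fit` objects (`resident`, `disperser`,
#'   `migrant`), each with `model_class`, `gamma0`, `delta`, `theta`, `phi`,
#'   `theta2`, `phi2`, `criterion` (AIC), `rss`, `converged`.
#' @export
fit_elevation_models <- function(day, elevation) {
  ok <- is.finite(day) & is.finite(elevation)
  day <- day[ok]
  elevation <- elevation[ok]
  n <- length(day)
  if (n < 60) stop("need at least 60 days of data", call. = FALSE)

  aic_gauss <- function(rss, k) n * log(rss / n) + 2 * k

  nsd_fit <- function(model_class, pars, rss, k, converged) {
    structure(
      c(
        list(model_class = model_class),
        pars,
        list(
          rss = rss, n = n,
          criterion = if (converged) aic_gauss(rss, k) else Inf,
          converged = converged
        )
      ),
      class = "nsd_fit"
    )
  }

  # resident: closed form
  g0 <- mean(elevation)
  rss_res <- sum((elevation - g0)^2)
  res <- nsd_fit(
    "resident",
    list(
      gamma0 = g0, delta = 0, theta = NA_real_, phi = NA_real_,
      theta2 = NA_real_, phi2 = NA_real_
    ),
    rss_res, 2, TRUE
  )

  rng <- range(day)
  span <- diff(rng)
  theta_grid <- seq(rng[1] + 0.1 * span, rng[2] - 0.1 * span, length.out = 5)
  amp0 <- max(elevation) - min(elevation)

  best_nls <- function(formula, starts, lower, upper) {
    best <- NULL
    for (st in starts) {
      f <- tryCatch(
        suppressWarnings(minpack.lm::nlsLM(
          formula,
          data = data.frame(day = day, elevation = elevation),
          start = st, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )),
        error = function(e) NULL
      )
      if (!is.null(f)) {
        rss <- sum(stats::resid(f)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
      }
    }
    best
  }

  # disperser: single logistic rise
  disp_starts <- lapply(theta_grid, function(th) {
    list(gamma0 = min(elevation), delta = amp0, theta = th, phi = 5)
  })
  db <- best_nls(
    elevation ~ gamma0 + delta / (1 + exp((theta - day) / phi)),
    disp_starts,
    lower = c(gamma0 = -10000, delta = 0, theta = rng[1], phi = 0.1),
    upper = c(gamma0 = 10000, delta = 10000, theta = rng[2], phi = span / 2)
  )
  disp <- if (is.null(db)) {
    nsd_fit("disperser", list(
      gamma0 = NA_real_, delta = NA_real_, theta = NA_real_,
      phi = NA_real_, theta2 = NA_real_, phi2 = NA_real_
    ), NA_real_, 5, FALSE)
  } else {
    cf <- stats::coef(db$fit)
    nsd_fit("disperser", list(
      gamma0 = cf[["gamma0"]], delta = cf[["delta"]], theta = cf[["theta"]],
      phi = cf[["phi"]], theta2 = NA_real_, phi2 = NA_real_
    ), db$rss, 5, TRUE)
  }

  # migrant: rise and return; theta2 = theta + gap keeps theta2 > theta
  mig_starts <- lapply(theta_grid, function(th) {
    list(
      gamma0 = min(elevation), delta = amp0, theta = th, phi = 5,
      gap = max(span / 3, 30), phi2 = 5
    )
  })
  mb <- best_nls(
    elevation ~ gamma0 + delta / (1 + exp((theta - day) / phi)) -
      delta / (1 + exp((theta + gap - day) / phi2)),
    mig_starts,
    lower = c(gamma0 = -10000, delta = 0, theta = rng[1], phi = 0.1, gap = 5, phi2 = 0.1),
    upper = c(
      gamma0 = 10000, delta = 10000, theta = rng[2], phi = span / 2,
      gap = span, phi2 = span / 2
    )
  )
  mig <- if (is.null(mb)) {
    nsd_fit("migrant", list(
      gamma0 = NA_real_, delta = NA_real_, theta = NA_real_,
      phi = NA_real_, theta2 = NA_real_, phi2 = NA_real_
    ), NA_real_, 7, FALSE)
  } else {
    cf <- stats::coef(mb$fit)
    nsd_fit("migrant", list(
      gamma0 = cf[["gamma0"]], delta = cf[["delta"]], theta = cf[["theta"]],
      phi = cf[["phi"]], theta2 = cf[["theta"]] + cf[["gap"]], phi2 = cf[["phi2"]]
    ), mb$rss, 7, TRUE)
  }

  list(resident = res, disperser = disp, migrant = mig)
}

#' @export
print.nsd_fit <- function(x, ...) {
  cat(sprintf(
    "<nsd_fit %s> gamma0 %.0f m, delta %.0f m, theta %.1f, phi %.2f d, AIC %.1f%s\n",
    x$model_class, x$gamma0, x$delta %||% 0, x$theta %||% NA, x$phi %||% NA,
    x$criterion, if (!x$converged) " [NOT CONVERGED]" else ""
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# days the fitted curve spends within 5% of delta of each asymptote, in the
# right temporal order: the low (pre-migration) range before theta, the high
# (post-migration) range after theta and -- for migrants -- before the return
# at theta2. Ordering matters: without it a pure descent (first logistic
# pinned before the data) would satisfy both residence checks.
plateau_occupancy <- function(fit, day) {
  pred <- fit$gamma0 + fit$delta / (1 + exp((fit$theta - day) / fit$phi))
  high_until <- Inf
  if (!is.na(fit$theta2)) {
    pred <- pred - fit$delta / (1 + exp((fit$theta2 - day) / fit$phi2))
    high_until <- fit$theta2
  }
  tol <- 0.05 * fit$delta
  low_days <- sum(abs(pred - fit$gamma0) <= tol & day < fit$theta)
  high_days <- sum(
    abs(pred - (fit$gamma0 + fit$delta)) <= tol &
      day > fit$theta & day < high_until
  )
  c(low = low_days, high = high_days)
}

#' Classify an animal-year's migratory strategy
#'
#' The best-criterion candidate wins, then threshold demotions apply:
#' migrant/disperser winners with displacement `delta` below `min_delta`
#' (500 m) or with less than `min_rho` (21) days of fitted residence on
#' either seasonal range are demoted to resident. Uphill dispersers are
#' relabelled migrants (the study concerns uphill spring migration); the
#' single-logistic candidate only represents uphill moves (`delta >= 0` by
#' construction), so dispersers surviving the thresholds always join the
#' migrant class. Ties in the criterion break toward the simpler model.
#'
#' @param fits list from [fit_elevation_models()].
#' @param day the day vector the models were fit to (for plateau
#'   occupancy).
#' @param min_delta minimum displacement between seasonal ranges (m).
#' @param min_rho minimum residence on each seasonal range (days).
#' @return a one-row tibble: `class` (`resident`/`migrant`), `model_class`
#'   (the winning curve before relabelling), `gamma0`, `delta`, `theta`,
#'   `phi`, `theta2`, `phi2`, `criterion`.
#' @export
classify_strategy <- function(fits, day, min_delta = 500, min_rho = 21) {
  if (!fits$resident$converged) {
    stop("resident fit did not converge; cannot classify", call. = FALSE)
  }
  cand <- Filter(function(f) f$converged, fits)
  # ties toward the simpler model: resident < disperser < migrant order
  order_pref <- c(resident = 1, disperser = 2, migrant = 3)
  crit <- vapply(cand, function(f) f$criterion, numeric(1))
  pref <- order_pref[vapply(cand, function(f) f$model_class, character(1))]
  win <- cand[[order(crit, pref)[1]]]

  cls <- win$model_class
  if (cls %in% c("disperser", "migrant")) {
    occ <- plateau_occupancy(win, day)
    if (win$delta < min_delta || any(occ < min_rho)) {
      win <- fits$resident
      cls <- "resident"
    }
  }
  final <- switch(cls,
    resident = "resident",
    disperser = "migrant", # uphill dispersers join the migrant class
    migrant = "migrant"
  )
  tibble::tibble(
    class = final, model_class = cls,
    gamma0 = win$gamma0, delta = win$delta,
    theta = win$theta, phi = win$phi,
    theta2 = win$theta2, phi2 = win$phi2,
    criterion = win$criterion
  )
}

#' Migration window, duration, and tactic
#'
#' Duration is the logistic 5--95 percent traverse time,
#' `2 * phi * ln(19)`; migrations lasting under 7 days are "fast", at least
#' 7 days "slow". The habitat-selection analysis window is the 21 days
#' centred on `theta`.
#'
#' @param theta migration midpoint (day).
#' @param phi migration timescale (days, > 0).
#' @return a one-row tibble: `theta`, `duration_days`, `is_fast`,
#'   `window_start`, `window_end` (each `theta +- 10.5`).
#' @examples
#' migration_window(150, 1) # ~5.89 days: a fast migrant
#' @export
migration_window <- function(theta, phi) {
  if (any(!is.finite(theta)) || any(!is.finite(phi)) || any(phi <= 0)) {
    stop("migration_window needs a migrant fit (finite theta, phi > 0)",
      call. = FALSE
    )
  }
  duration <- 2 * phi * log(19)
  tibble::tibble(
    theta = theta,
    duration_days = duration,
    is_fast = duration < 7,
    window_start = theta - 10.5,
    window_end = theta + 10.5
  )
}

#' Classify every animal-year in a fix table
#'
#' Daily-averages the elevation under each animal-year's fixes (DEM value at
#' the fix location) and runs the model comparison and threshold rules.
#'
#' @param fixes fix table with `animal_id`, `doy` (or `timestamp`), `x`,
#'   `y`, optional `year` (defaults to a single year) and grouping columns.
#' @param dem elevation [raster_grid()].
#' @param min_delta,min_rho classification thresholds (m, days).
#' @return a tibble, one row per animal-year, as [classify_strategy()] plus
#'   `animal_id`, `year`, `duration_days`, `is_fast` (migrants only) and any
#'   carried `herd_unit`/`sex`.
#' @export
classify_migration <- function(fixes, dem, min_delta = 500, min_rho = 21) {
  if (!"doy" %in% names(fixes)) {
    fixes$doy <- as.numeric(strftime(fixes$timestamp, "%j"))
  }
  if (!"year" %in% names(fixes)) fixes$year <- 1L
  fixes$elev <- rg_extract(dem, fixes$x, fixes$y)
  carry <- intersect(c("herd_unit", "sex"), names(fixes))

  fixes |>
    dplyr::group_by(.data$animal_id, .data$year) |>
    dplyr::group_modify(function(df, key) {
      daily <- df |>
        dplyr::mutate(day = floor(.data$doy)) |>
        dplyr::group_by(.data$day) |>
        dplyr::summarise(elevation = mean(.data$elev), .groups = "drop")
      rec <- tryCatch(
        {
          fits <- fit_elevation_models(daily$day, daily$elevation)
          classify_strategy(fits, daily$day, min_delta, min_rho)
        },
        error = function(e) NULL
      )
      if (is.null(rec)) {
        return(tibble::tibble(class = NA_character_))
      }
      if (rec$class == "migrant") {
        win <- migration_window(rec$theta, rec$phi)
        rec$duration_days <- win$duration_days
        rec$is_fast <- win$is_fast
      } else {
        rec$duration_days <- NA_real_
        rec$is_fast <- NA
      }
      for (cc in carry) rec[[cc]] <- df[[cc]][1]
      rec
    }) |>
    dplyr::ungroup()
}

#' Between-year switch rates
#'
#' For each individual with at least two classified years, the fraction of
#' consecutive-year pairs whose strategy (resident vs migrant) differs, and
#' -- among pairs where both years are migratory -- whose tactic (fast vs
#' slow) differs. Population mean and standard error are taken over
#' individuals.
#'
#' @param records tibble with `animal_id`, `year`, `class` and (for
#'   migrants) `is_fast`.
#' @return a tibble with `metric` (`strategy`/`rate`), `mean`, `se`,
#'   `n_individuals`.
#' @export
switch_rates <- function(records) {
  per <- records |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::summarise(
      n_years = dplyr::n(),
      strategy = if (dplyr::n() >= 2) {
        mean(utils::head(.data$class, -1) != utils::tail(.data$class, -1))
      } else {
        NA_real_
      },
      rate = {
        both_mig <- utils::head(.data$class, -1) == "migrant" &
          utils::tail(.data$class, -1) == "migrant"
        if (any(both_mig, na.rm = TRUE)) {
          mean((utils::head(.data$is_fast, -1) != utils::tail(.data$is_fast, -1))[both_mig])
        } else {
          NA_real_
        }
      },
      .groups = "drop"
    )
  summarise_metric <- function(v, label) {
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      stop("no individuals with enough classified years for the ", label,
        " switch rate",
        call. = FALSE
      )
    }
    tibble::tibble(
      metric = label, mean = mean(v),
      se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      n_individuals = length(v)
    )
  }
  dplyr::bind_rows(
    summarise_metric(per$strategy, "strategy"),
    summarise_metric(per$rate, "rate")
  )
}
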