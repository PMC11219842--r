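mk_fixes <- function(hours, x = NULL, y = NULL, id = "a1") {
  t0 <- as.POSIXct("2021-04-01 00:00:00", tz = "UTC")
  tibble::tibble(
    animal_id = id,
    timestamp = t0 + hours * 3600,
    x = if (is.null(x)) seq_along(hours) * 10 else x,
    y = if (is.null(y)) rep(0, length(hours)) else y
  )
}

test_that("rarefaction keeps one fix per 12-h slot and is idempotent", {
  hourly <- mk_fixes(0:48)
  r <- rarify_track(hourly)
  expect_equal(nrow(r), 5)
  expect_equal(
    as.numeric(difftime(r$timestamp, hourly$timestamp[1], units = "hours")),
    c(0, 12, 24, 36, 48)
  )
  # already 12-h data pass through unchanged
  twelve <- mk_fixes(seq(0, 96, by = 12))
  r2 <- rarify_track(twelve)
  expect_equal(r2$timestamp, twelve$timestamp)
  expect_equal(rarify_track(r2)$timestamp, r2$timestamp) # idempotent
  # off-slot fixes within tolerance are snapped to the nearest slot
  jitter <- mk_fixes(c(0, 11, 25, 36.5))
  expect_equal(nrow(rarify_track(jitter)), 4)
  # a fix 6 h off every slot is discarded
  off <- mk_fixes(c(0, 6, 12))
  expect_equal(nrow(rarify_track(off)), 2)
})

test_that("steps are not formed across slot gaps", {
  gappy <- mk_fixes(c(0, 12, 36, 48)) # 24-h hole between slots 1 and 3
  st <- build_steps(rarify_track(gappy))
  expect_equal(nrow(st), 2)
  expect_equal(st$slot, c(0, 3))
  # the step after the gap has no defined turning angle (new burst)
  expect_true(all(is.na(st$turn_angle) | st$slot == 0 | st$slot != 3))
})

test_that("step geometry: length, heading and signed turn angles", {
  hrs <- seq(0, 36, by = 12)
  # east, east, then a left turn to north
  fx <- mk_fixes(hrs, x = c(0, 3, 6, 6), y = c(0, 4, 8, 108))
  st <- build_steps(rarify_track(fx))
  expect_equal(st$length[1], 5) # 3-4-5
  expect_true(is.na(st$turn_angle[1])) # needs three fixes
  expect_equal(st$turn_angle[2], 0) # collinear
  # last step turns from heading atan2(4,3) to pi/2
  expect_equal(st$turn_angle[3], pi / 2 - atan2(4, 3), tolerance = 1e-12)
  # pure right-angle left turn is +pi/2
  fx2 <- mk_fixes(hrs[1:3], x = c(0, 10, 10), y = c(0, 0, 10))
  st2 <- build_steps(rarify_track(fx2))
  expect_equal(st2$turn_angle[2], pi / 2)
})

test_that("kernel MLE recovers gamma and von Mises parameters", {
  set.seed(21)
  steps <- tibble::tibble(
    length = rgamma(5000, shape = 2, scale = 100),
    turn_angle = rvonmises(5000, mu = 0.3, kappa = 1.5)
  )
  k <- fit_movement_kernel(steps)
  expect_lt(abs(k$gamma_shape - 2) / 2, 0.05)
  expect_lt(abs(k$gamma_scale - 100) / 100, 0.05)
  expect_lt(abs(k$vm_kappa - 1.5) / 1.5, 0.1)
  expect_lt(abs(k$vm_mu - 0.3), 0.1)
  # uniform angles: concentration near zero
  set.seed(22)
  u <- tibble::tibble(
    length = rgamma(10000, 2, scale = 50),
    turn_angle = runif(10000, -pi, pi)
  )
  expect_lt(fit_movement_kernel(u)$vm_kappa, 0.05)
  # nearly constant angles hit the concentration cap
  c0 <- tibble::tibble(
    length = rgamma(100, 2, scale = 50),
    turn_angle = rep(c(0, 1e-9), 50)
  )
  expect_equal(fit_movement_kernel(c0)$vm_kappa, 500)
  # degenerate inputs are refused
  expect_error(
    fit_movement_kernel(tibble::tibble(length = 1, turn_angle = 0.2)),
    "at least"
  )
})

test_that("gamma MLE agrees with fitdistrplus on a shared sample", {
  skip_if_not_installed("fitdistrplus")
  set.seed(9)
  x <- rgamma(2000, shape = 3.2, scale = 40)
  ours <- fit_gamma(x)
  ref <- fitdistrplus::fitdist(x, "gamma")
  # the reference optimiser itself converges to ~1e-3 relative precision
  expect_equal(ours$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(1 / ours$scale, unname(ref$estimate["rate"]), tolerance = 1e-3)
})

test_that("available-step sampling builds balanced, reproducible strata", {
  set.seed(5)
  fx <- mk_fixes(seq(0, 240, by = 12),
    x = cumsum(c(0, rgamma(20, 2, scale = 80))) + 2000,
    y = 2000 + cumsum(c(0, rnorm(20, 0, 60)))
  )
  st <- build_steps(rarify_track(fx))
  kern <- list(gamma_shape = 2, gamma_scale = 80, vm_mu = 0, vm_kappa = 0.5)
  s1 <- sample_available(st, kern, k = 30, seed = 42)
  # 31 members per stratum, exactly one used
  counts <- table(s1$stratum_id)
  expect_true(all(counts == 31))
  expect_true(all(tapply(s1$case, s1$stratum_id, sum) == 1))
  # only steps with a defined previous heading form strata
  expect_equal(length(counts), sum(is.finite(st$turn_angle)))
  # determinism under a fixed seed
  s2 <- sample_available(st, kern, k = 30, seed = 42)
  expect_identical(s1$x, s2$x)
  # a huge concentration pins endpoints to the previous heading
  kinf <- list(gamma_shape = 2, gamma_scale = 80, vm_mu = 0, vm_kappa = 1e8)
  s3 <- sample_available(st, kinf, k = 5, seed = 1)
  avail <- s3[s3$case == 0, ]
  prev <- st$prev_heading[match(avail$stratum_id, st$step_id)]
  bearing <- atan2(avail$y - avail$y1, avail$x - avail$x1)
  expect_lt(max(abs(wrap_angle(bearing - prev))), 1e-3)
})

test_that("pooled available lengths and angles match the generating kernel", {
  set.seed(77)
  fx <- mk_fixes(seq(0, 1200, by = 12),
    x = cumsum(c(0, rgamma(100, 2, scale = 80))) + 5000,
    y = 5000 + cumsum(c(0, rnorm(100, 0, 60)))
  )
  st <- build_steps(rarify_track(fx))
  kern <- list(gamma_shape = 2, gamma_scale = 120, vm_mu = 0, vm_kappa = 0.8)
  s <- sample_available(st, kern, k = 30, seed = 3)
  avail <- s[s$case == 0, ]
  ks_len <- ks.test(avail$sl, pgamma, shape = 2, scale = 120)
  expect_gt(ks_len$p.value, 0.01)
})

test_that("covariate transforms follow the field-standard conventions", {
  # hot-day threshold: linear-interpolation 75th percentile of {1..100}
  n_strata <- 100
  k <- 2
  raw <- tibble::tibble(
    stratum_id = rep(seq_len(n_strata), each = k + 1),
    case = rep(c(1L, 0L, 0L), n_strata),
    animal_id = "a1",
    elevation = rnorm(n_strata * (k + 1), 2000, 300),
    slope = runif(n_strata * (k + 1), 0, 60),
    cos_aspect = runif(n_strata * (k + 1), -1, 1),
    dist_escape = rexp(n_strata * (k + 1), 1 / 200),
    tmax = rnorm(n_strata * (k + 1), 15, 5),
    precip = 0,
    fsc = runif(n_strata * (k + 1), 0, 100),
    dist_snow = rexp(n_strata * (k + 1), 1 / 500),
    days_since_snowmelt = rnorm(n_strata * (k + 1), 30, 10),
    abs_ndvi = runif(n_strata * (k + 1), 0, 0.8),
    rel_ndvi = runif(n_strata * (k + 1)),
    days_since_greenup = rnorm(n_strata * (k + 1), -10, 20),
    tmax_start = rep(1:100, each = k + 1),
    precip_start = rep(c(0, 5), length.out = n_strata * (k + 1))
  )
  tr <- transform_covariates(raw)
  # z-scored columns have mean 0, sd 1 over the whole design
  expect_lt(abs(mean(tr$elevation_z)), 1e-9)
  expect_lt(abs(sd(tr$elevation_z) - 1), 1e-9)
  expect_lt(abs(mean(tr$tmax_z)), 1e-9)
  # log1p leaves zeros at zero
  expect_true(all(tr$log1p_precip == 0))
  # hot threshold 75.25 for startpoint temps 1..100
  expect_equal(sort(unique(tr$hot_start[tr$tmax_start > 75.25])), 1L)
  expect_equal(sort(unique(tr$hot_start[tr$tmax_start <= 75.25])), 0L)
  # interactions are exact products
  expect_equal(tr$elev_x_hot, tr$elevation_z * tr$hot_start)
  expect_equal(tr$elev_x_rain, tr$elevation_z * tr$rain_start)
  expect_equal(unique(tr$rain_start[tr$precip_start == 0]), 0L)
  # incomplete strata are dropped whole
  raw2 <- raw
  raw2$fsc[5] <- NA
  tr2 <- transform_covariates(raw2)
  expect_equal(attr(tr2, "n_dropped_strata"), 1)
  expect_true(all(table(tr2$stratum_id) == k + 1))
  # zero-variance z columns error
  raw3 <- raw
  raw3$slope <- 10
  expect_error(transform_covariates(raw3), "zero variance")
})

test_that("individuals are balanced to the minimum stratum count", {
  d <- tibble::tibble(
    animal_id = rep(c("a", "b"), times = c(60, 30)),
    stratum_id = c(rep(1:20, each = 3), rep(21:30, each = 3)),
    case = rep(c(1, 0, 0), 30)
  )
  b <- balance_individuals(d, seed = 4)
  tab <- b |>
    dplyr::distinct(animal_id, stratum_id) |>
    dplyr::count(animal_id)
  expect_true(all(tab$n == 10))
  expect_true(all(table(b$stratum_id) == 3)) # strata stay intact
})
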