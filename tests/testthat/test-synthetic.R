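test_that("scenario validation enforces the stated invariants", {
  expect_error(migration_scenario(elevation_range = c(3000, 1500)), "min <= max")
  expect_error(migration_scenario(n_proposals = 1), "at least 2")
  expect_error(migration_scenario(cell_size = 0), "positive")
  expect_error(migration_scenario(truth_betas = c(1, 2)), "named")
})

test_that("generators are bit-identical under a repeated seed", {
  sc <- migration_scenario(seed = 13, grid_size = c(20, 20), cell_size = 300)
  expect_identical(make_landscape(sc)$values, make_landscape(sc)$values)
  dem <- make_landscape(sc)
  f1 <- make_dynamic_fields(sc, dem)
  f2 <- make_dynamic_fields(sc, dem)
  expect_identical(f1$tmax$values, f2$tmax$values)
  expect_identical(f1$fsc$values, f2$fsc$values)
  expect_identical(f1$ndvi$values, f2$ndvi$values)
  w <- prepare_sim_world(sc, dem, f1)
  t1 <- simulate_issf_track(sc, w, start = c(3000, 3000), seed = 8)
  t2 <- simulate_issf_track(sc, w, start = c(3000, 3000), seed = 8)
  expect_identical(t1$x, t2$x)
})

test_that("degenerate and analytic landscapes behave as constructed", {
  flat <- migration_scenario(
    seed = 1, grid_size = c(10, 10),
    elevation_range = c(0, 0)
  )
  expect_true(all(make_landscape(flat)$values == 0))
  # pure linear gradient: 1000 m rise over (101 - 1) * 100 m = 10 km
  sc <- migration_scenario(
    seed = 1, grid_size = c(5, 101), cell_size = 100,
    elevation_range = c(0, 1000), ridge_amp = 0
  )
  dem <- make_landscape(sc)
  slope <- slope_aspect(dem)$slope
  expect_equal(max(abs(slope$values - atan(0.1) * 180 / pi)), 0,
    tolerance = 1e-9
  )
})

test_that("dynamic fields encode the lapse rate, events and phenology", {
  sc <- migration_scenario(seed = 4, grid_size = c(12, 12), cell_size = 400)
  dem <- make_landscape(sc)
  f <- make_dynamic_fields(sc, dem)
  # two pixels, same day: tmax difference = lapse * elevation difference
  i1 <- c(2, 2)
  i2 <- c(10, 11)
  dz <- dem$values[i2[1], i2[2]] - dem$values[i1[1], i1[2]]
  dt <- f$tmax$values[i2[1], i2[2], 150] - f$tmax$values[i1[1], i1[2], 150]
  expect_equal(dt, -0.0065 * dz, tolerance = 1e-9)
  # zero event probability: all-zero precipitation stack
  sc0 <- migration_scenario(
    seed = 4, grid_size = c(6, 6),
    weather = list(precip_prob = 0)
  )
  f0 <- make_dynamic_fields(sc0, make_landscape(sc0))
  expect_true(all(f0$precip$values == 0))
  # FSC lives on [0, 100] and NDVI within [-1, 1]
  expect_true(all(f$fsc$values >= 0 & f$fsc$values <= 100))
  expect_true(all(abs(f$ndvi$values) <= 1))
})

test_that("null selection picks proposals uniformly", {
  sc <- migration_scenario(
    seed = 10, grid_size = c(60, 60), cell_size = 400,
    n_steps = 2000, n_proposals = 20, truth_betas = c(elevation_z = 0)
  )
  dem <- make_landscape(sc)
  f <- make_dynamic_fields(sc, dem)
  # this gentle 400-m-cell landscape has no escape terrain; the empty-mask
  # warning is expected and the covariate is unused under beta = NULL
  w <- suppressWarnings(prepare_sim_world(sc, dem, f))
  res <- simulate_issf_track(sc, w,
    beta = NULL, start = c(12000, 12000),
    seed = 6, detail = TRUE
  )
  tab <- tabulate(res$choices$chosen, nbins = 20)
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("strong elevation selection drives tracks uphill", {
  sc <- migration_scenario(
    seed = 12, grid_size = c(50, 50), cell_size = 200,
    n_steps = 40, truth_betas = c(elevation_z = 5)
  )
  dem <- make_landscape(sc)
  f <- make_dynamic_fields(sc, dem)
  w <- prepare_sim_world(sc, dem, f)
  ups <- vapply(1:100, function(r) {
    tr <- simulate_issf_track(sc, w, start = c(1500, 5000), seed = 100 + r)
    elev <- rg_extract(dem, tr$x, tr$y)
    elev[length(elev)] > elev[1]
  }, logical(1))
  expect_gte(mean(ups), 0.95)
})

test_that("beta = 0 track step lengths match the generating gamma", {
  sc <- migration_scenario(
    seed = 14, grid_size = c(60, 60), cell_size = 400,
    n_steps = 300, n_animals = 1
  )
  dem <- make_landscape(sc)
  f <- make_dynamic_fields(sc, dem)
  w <- suppressWarnings(prepare_sim_world(sc, dem, f)) # no escape terrain here
  pass <- vapply(1:20, function(r) {
    tr <- simulate_issf_track(sc, w,
      beta = NULL, start = c(12000, 12000),
      seed = 500 + r
    )
    sl <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    suppressWarnings(
      ks.test(sl, pgamma, shape = sc$kernel$shape, scale = sc$kernel$scale)$p.value
    ) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("elevation profiles honour their generating parameters", {
  # flat resident: OLS slope indistinguishable from zero
  pr <- simulate_elevation_profile("resident", noise_sd = 40, seed = 2)
  sl <- summary(lm(elevation ~ day, pr))$coefficients["day", ]
  expect_lt(abs(sl["Estimate"]), 2 * sl["Std. Error"])
  # noiseless migrant sits exactly delta / 2 above baseline at theta
  pm <- simulate_elevation_profile("migrant",
    delta = 1000, theta = 150, phi = 5,
    noise_sd = 0, descend = FALSE, elev0 = 1800
  )
  expect_equal(pm$elevation[pm$day == 150], 1800 + 500, tolerance = 1e-9)
  # residual RMSE about the true curve matches the noise level within 20%
  pn <- simulate_elevation_profile("migrant",
    delta = 1200, theta = 140, phi = 6,
    noise_sd = 50, seed = 11
  )
  mu <- simulate_elevation_profile("migrant",
    delta = 1200, theta = 140, phi = 6,
    noise_sd = 0, seed = 11
  )
  rmse <- sqrt(mean((pn$elevation - mu$elevation)^2))
  expect_lt(abs(rmse - 50) / 50, 0.2)
  expect_error(simulate_elevation_profile("migrant", phi = 0), "positive")
})

test_that("fix tables round-trip through CSV", {
  fx <- tibble::tibble(
    animal_id = c("a1", "a1", "b2"),
    timestamp = as.POSIXct("2021-05-01 06:00:00", tz = "UTC") + c(0, 43200, 0),
    x = c(1000, 1400, 2000), y = c(500, 800, 900),
    herd_unit = c("h1", "h1", "h2")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixes(fx, path)
  fx2 <- read_fixes(path)
  expect_equal(fx2$timestamp, fx$timestamp)
  expect_equal(fx2$x, fx$x)
  expect_equal(fx2$herd_unit, fx$herd_unit)
})
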