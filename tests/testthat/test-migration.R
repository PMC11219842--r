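test_that("generative profiles are classified by their own model family", {
  # flat noisy series: resident has the lowest criterion
  pr <- simulate_elevation_profile("resident", noise_sd = 50, seed = 3)
  fits <- fit_elevation_models(pr$day, pr$elevation)
  crit <- vapply(fits, function(f) f$criterion, numeric(1))
  expect_equal(names(which.min(crit)), "resident")
  rec <- classify_strategy(fits, pr$day)
  expect_equal(rec$class, "resident")

  # rise-then-fall profile: migrant beats disperser and recovers theta
  pm <- simulate_elevation_profile("migrant",
    delta = 1000, theta = 150, phi = 5,
    noise_sd = 50, seed = 4
  )
  fm <- fit_elevation_models(pm$day, pm$elevation)
  expect_lt(fm$migrant$criterion, fm$disperser$criterion)
  expect_lt(abs(fm$migrant$theta - 150), 2)
  recm <- classify_strategy(fm, pm$day)
  expect_equal(recm$class, "migrant")
  expect_equal(recm$model_class, "migrant")

  # clean single rise: the disperser curve recovers theta and joins the
  # migrant class after thresholding
  pd <- simulate_elevation_profile("migrant",
    delta = 1000, theta = 150, phi = 5,
    noise_sd = 30, descend = FALSE, seed = 5
  )
  fd <- fit_elevation_models(pd$day, pd$elevation)
  expect_lt(abs(fd$disperser$theta - 150), 2)
  recd <- classify_strategy(fd, pd$day)
  expect_equal(recd$class, "migrant")
})

test_that("threshold demotions and the uphill-only rule apply", {
  # a 300 m rise is below the 500 m range separation: demoted to resident
  p3 <- simulate_elevation_profile("migrant",
    delta = 300, theta = 150, phi = 5,
    noise_sd = 40, seed = 6
  )
  f3 <- fit_elevation_models(p3$day, p3$elevation)
  expect_equal(classify_strategy(f3, p3$day)$class, "resident")

  # a 1200 m rise with long plateaus is a migrant
  p12 <- simulate_elevation_profile("migrant",
    delta = 1200, theta = 150, phi = 4,
    noise_sd = 40, seed = 7
  )
  f12 <- fit_elevation_models(p12$day, p12$elevation)
  expect_equal(classify_strategy(f12, p12$day)$class, "migrant")

  # a downhill mover never becomes a migrant (uphill-only relabelling)
  down <- simulate_elevation_profile("migrant",
    delta = 1000, theta = 150, phi = 5,
    noise_sd = 40, descend = FALSE, seed = 8
  )
  down$elevation <- 4000 - (down$elevation - min(down$elevation))
  fdn <- fit_elevation_models(down$day, down$elevation)
  expect_false(identical(classify_strategy(fdn, down$day)$class, "migrant"))

  # a brief spike (< 21 days on the upper range) is demoted to resident
  spike <- simulate_elevation_profile("migrant",
    delta = 800, theta = 150, phi = 2,
    theta2 = 160, phi2 = 2, noise_sd = 40, seed = 9
  )
  fsp <- fit_elevation_models(spike$day, spike$elevation)
  expect_equal(classify_strategy(fsp, spike$day)$class, "resident")
})

test_that("classification is invariant to a constant elevation shift", {
  p <- simulate_elevation_profile("migrant",
    delta = 900, theta = 145, phi = 6,
    noise_sd = 40, seed = 10
  )
  f1 <- fit_elevation_models(p$day, p$elevation)
  f2 <- fit_elevation_models(p$day, p$elevation + 750)
  r1 <- classify_strategy(f1, p$day)
  r2 <- classify_strategy(f2, p$day)
  expect_equal(r1$class, r2$class)
  expect_equal(r1$theta, r2$theta, tolerance = 1e-3)
  expect_equal(r2$gamma0 - r1$gamma0, 750, tolerance = 1)
})

test_that("duration follows the 5-95% logistic traverse rule", {
  w1 <- migration_window(150, 1)
  expect_equal(w1$duration_days, 2 * log(19), tolerance = 1e-12)
  expect_true(w1$is_fast) # ~5.89 days < 7
  w2 <- migration_window(150, 2)
  expect_equal(w2$duration_days, 4 * log(19), tolerance = 1e-12)
  expect_false(w2$is_fast) # ~11.78 days
  # the limit phi -> 0+ is instantaneous and fast
  w0 <- migration_window(150, 1e-9)
  expect_lt(w0$duration_days, 1e-6)
  expect_true(w0$is_fast)
  expect_equal(w1$window_start, 139.5)
  expect_equal(w1$window_end, 160.5)
  expect_error(migration_window(150, 0), "migrant")
})

test_that("switch rates aggregate consecutive-year changes", {
  rec <- tibble::tibble(
    animal_id = c(rep("m1", 4), rep("m2", 3), rep("m3", 2)),
    year = c(1:4, 1:3, 1:2),
    class = c(
      "migrant", "resident", "migrant", "resident", # alternating
      "migrant", "migrant", "migrant", # constant
      "migrant", "migrant"
    ),
    is_fast = c(
      TRUE, NA, FALSE, NA,
      TRUE, TRUE, TRUE,
      TRUE, FALSE
    )
  )
  sr <- switch_rates(rec)
  strat <- sr[sr$metric == "strategy", ]
  expect_equal(strat$mean, mean(c(1, 0, 0)))
  rate <- sr[sr$metric == "rate", ]
  # m2 never switches tactic (0), m3 switches (1): mean 0.5, SE 0.5
  expect_equal(rate$mean, 0.5)
  expect_equal(rate$se, 0.5)
  expect_equal(rate$n_individuals, 2)
  # single-year individuals cannot contribute
  expect_error(
    switch_rates(tibble::tibble(
      animal_id = "x", year = 1, class = "migrant", is_fast = TRUE
    )),
    "enough classified years"
  )
})

test_that("classify_migration runs per animal-year over a fix table", {
  sc <- migration_scenario(seed = 20, grid_size = c(30, 30), cell_size = 300)
  dem <- make_landscape(sc)
  mkfx <- function(id, cls, seed) {
    p <- simulate_elevation_profile(cls,
      delta = 1000, theta = 150, phi = 4,
      noise_sd = 30, seed = seed, elev0 = 1700
    )
    # place fixes at grid cells whose elevation tracks the profile
    ix <- vapply(p$elevation, function(e) which.min(abs(dem$values - e)), integer(1))
    rc <- arrayInd(ix, dim(dem$values))
    tibble::tibble(
      animal_id = id, doy = p$day, year = 1L,
      x = (rc[, 2] - 0.5) * 300, y = (rc[, 1] - 0.5) * 300,
      herd_unit = "h1"
    )
  }
  fixes <- dplyr::bind_rows(
    mkfx("mig1", "migrant", 31),
    mkfx("res1", "resident", 32)
  )
  recs <- classify_migration(fixes, dem)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$class[recs$animal_id == "mig1"], "migrant")
  expect_equal(recs$class[recs$animal_id == "res1"], "resident")
  expect_false(is.na(recs$is_fast[recs$animal_id == "mig1"]))
})
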