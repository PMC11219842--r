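test_that("the null conditional log-likelihood is exact", {
  gs <- make_choice_strata(40, 30, beta = c(0.5, -0.5), seed = 2)
  fit <- fit_clogit(gs$data, gs$covariates)
  expect_identical(fit$loglik_null, -40 * log(31))
})

test_that("no within-stratum information leaves beta at zero", {
  # identical covariates inside every stratum: flat likelihood, beta = 0
  set.seed(1)
  d <- tibble::tibble(
    stratum_id = rep(1:25, each = 4),
    case = rep(c(1L, 0L, 0L, 0L), 25),
    animal_id = rep(1:5, each = 20),
    x1 = rep(rnorm(25), each = 4),
    x2 = rep(rnorm(25), each = 4)
  )
  fit <- fit_clogit(d, c("x1", "x2"))
  expect_equal(unname(fit$beta), c(0, 0))
  expect_identical(fit$loglik, -25 * log(4))
  expect_true(fit$converged)
  # a design where only one column is degenerate is rejected instead
  d$x3 <- rnorm(100)
  expect_error(fit_clogit(d, c("x1", "x3")), "rank deficient")
})

test_that("Newton estimates match the enumerated-likelihood oracle", {
  gs <- make_choice_strata(30, 10, beta = c(0.8, -0.3, 0.4), seed = 5)
  fit <- fit_clogit(gs$data, gs$covariates)
  orc <- oracle_clogit(gs$data, gs$covariates)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$beta - orc)), 1e-6)
  expect_lt(fit$grad_norm, 1e-8)
})

test_that("estimates agree with the survival package to near machine precision", {
  skip_if_not_installed("survival")
  gs <- make_choice_strata(60, 14, beta = c(-0.6, 0.9), seed = 7)
  fit <- fit_clogit(gs$data, gs$covariates)
  # conditional logistic = Cox partial likelihood with one event per stratum
  ref <- survival::coxph(
    survival::Surv(rep(1, nrow(gs$data)), case) ~ x1 + x2 +
      survival::strata(stratum_id),
    data = gs$data, method = "exact"
  )
  expect_lt(max(abs(fit$beta - coef(ref))), 1e-8)
  # model-based covariance agrees as well
  expect_lt(max(abs(fit$vcov_model - vcov(ref))), 1e-8)
})

test_that("perfect separation is detected and reported, not returned silently", {
  d <- tibble::tibble(
    stratum_id = rep(1:20, each = 3),
    case = rep(c(1L, 0L, 0L), 20),
    animal_id = 1,
    x1 = rep(c(1, 0, 0), 20) + rnorm(60, 0, 1e-3) # used always largest
  )
  fit <- fit_clogit(d, "x1")
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("QIC reduces to AIC under equal variances and scales with the meat", {
  gs <- make_choice_strata(50, 8, beta = c(0.5, -0.5, 0.2), seed = 9)
  fit <- fit_clogit(gs$data, gs$covariates)
  p <- length(fit$beta)
  # equal vcovs: penalty is exactly 2p
  f_eq <- fit
  f_eq$vcov_robust <- f_eq$vcov_model
  expect_equal(qic(f_eq), -2 * f_eq$loglik + 2 * p, tolerance = 1e-10)
  # inflating the robust variance doubles the penalty term
  f2 <- fit
  f2$vcov_robust <- 2 * fit$vcov_robust
  pen1 <- qic(fit) + 2 * fit$loglik
  pen2 <- qic(f2) + 2 * fit$loglik
  expect_equal(pen2, 2 * pen1, tolerance = 1e-10)
})

test_that("Newton iterations are monotone on the concave likelihood", {
  gs <- make_choice_strata(40, 12, beta = c(1.2, -0.8, 0.5, 0.3), seed = 11)
  fit <- fit_clogit(gs$data, gs$covariates)
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_null) # starting value never decreases
  expect_lt(fit$grad_norm, 1e-8)
})

test_that("analysis windows follow the migrant / resident / exclusion rules", {
  strategies <- tibble::tibble(
    animal_id = c("m1", "m2", "r1", "r2"),
    year = 1L,
    herd_unit = c("A", "A", "A", "B"),
    class = c("migrant", "migrant", "resident", "resident"),
    theta = c(140, 160, NA, NA)
  )
  fixes <- tidyr::expand_grid(
    animal_id = c("m1", "m2", "r1", "r2"),
    doy = seq(100, 200, by = 0.5)
  ) |>
    dplyr::mutate(year = 1L)
  win <- select_analysis_windows(strategies, fixes)
  # migrant window is theta +- 10.5 (m1 migrated at theta = 140)
  m1 <- win[win$animal_id == "m1", ]
  expect_equal(range(m1$doy), c(129.5, 150.5))
  # resident window centres on the herd-year mean theta (150)
  r1 <- win[win$animal_id == "r1", ]
  expect_equal(range(r1$doy), c(139.5, 160.5))
  expect_equal(mean(range(r1$doy)), 150)
  # resident in a herd-year without migrants is excluded
  expect_false("r2" %in% win$animal_id)
})

test_that("nested-model comparison ranks generative structure first", {
  set.seed(15)
  # two covariate blocks; only block A drives selection
  n_strata <- 150
  k <- 10
  rows <- (k + 1) * n_strata
  d <- tibble::tibble(
    stratum_id = rep(seq_len(n_strata), each = k + 1),
    animal_id = rep(rep(1:10, length.out = n_strata), each = k + 1),
    a1 = rnorm(rows), a2 = rnorm(rows),
    b1 = rnorm(rows), b2 = rnorm(rows)
  )
  eta <- 1.2 * d$a1 - 0.8 * d$a2
  d$case <- 0L
  for (s in seq_len(n_strata)) {
    i <- which(d$stratum_id == s)
    d$case[i[sample.int(k + 1, 1, prob = exp(eta[i] - max(eta[i])))]] <- 1L
  }
  cmp <- compare_nested(d, list(A = c("a1", "a2"), B = c("b1", "b2")))
  expect_equal(cmp$delta_qic[1], 0)
  expect_true(cmp$label[1] %in% c("overall", "A"))
  # the A-only model is within the parameter-penalty band of the overall fit
  dA <- cmp$qic[cmp$label == "A"] - cmp$qic[cmp$label == "overall"]
  expect_lt(abs(dA), 2 * 2 * 2) # 2 extra covariates, penalty band 2 * 2p
  # the B-only model is far worse
  expect_gt(cmp$qic[cmp$label == "B"] - cmp$qic[cmp$label == "A"], 50)
  # duplicate groupings give identical QICs with delta 0
  cmp2 <- compare_nested(d, list(A = c("a1", "a2"), A2 = c("a1", "a2")))
  expect_equal(
    cmp2$qic[cmp2$label == "A"], cmp2$qic[cmp2$label == "A2"],
    tolerance = 1e-9
  )
})

test_that("group models partition cleanly and report exponentiated effects", {
  gs <- make_choice_strata(240, 10, beta = c(0.7, -0.5), n_animals = 12, seed = 17)
  d <- gs$data
  d$group <- ifelse(d$animal_id <= 6, "female", "male")
  fits <- fit_group_models(d, gs$covariates, min_strata = 50)
  expect_named(fits, c("female", "male"), ignore.order = TRUE)
  # same generating beta: group estimates within 2 pooled SEs of each other
  for (cv in gs$covariates) {
    diff <- abs(fits$female$beta[cv] - fits$male$beta[cv])
    pooled <- sqrt(fits$female$se_model[cv]^2 + fits$male$se_model[cv]^2)
    expect_lt(diff, 2.5 * pooled)
  }
  # tidy reporting exposes exp(beta); a null effect displays as 1
  td <- tidy(fits$female, exponentiate = TRUE)
  expect_true("exp.estimate" %in% names(td))
  expect_equal(exp(0), 1)
  # undersized groups are skipped with a warning
  d$group[d$animal_id == 1] <- "tiny"
  expect_warning(
    f2 <- fit_group_models(d, gs$covariates, min_strata = 50),
    "skipped"
  )
  expect_false("tiny" %in% names(f2))
})

test_that("cross-validation is deterministic and calibrated", {
  gs <- make_choice_strata(200, 30, beta = c(2.5, -2), n_animals = 10, seed = 19)
  cv1 <- cross_validate(gs$data, gs$covariates, reps = 3, seed = 23)
  cv2 <- cross_validate(gs$data, gs$covariates, reps = 3, seed = 23)
  expect_identical(cv1$score, cv2$score)
  # null data scores near zero
  gs0 <- make_choice_strata(200, 30, beta = c(0, 0), n_animals = 10, seed = 21)
  cv0 <- cross_validate(gs0$data, gs0$covariates, reps = 3, seed = 23)
  expect_lt(abs(attr(cv0, "mean")), 2 * attr(cv0, "sd"))
})

test_that("strong selection on ample data scores above 0.9", {
  # the rank-frequency score needs enough held-out strata to populate all
  # 31 rank classes; ~400 test strata per fold suffices
  gs <- make_choice_strata(2000, 30, beta = c(1.5, -1), n_animals = 10, seed = 19)
  cv <- cross_validate(gs$data, gs$covariates, reps = 2, seed = 23)
  expect_gt(attr(cv, "mean"), 0.9)
})
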