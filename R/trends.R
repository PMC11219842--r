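#' Random-intercept linear mixed model
#'
#' Gaussian mixed model with one or two crossed random-intercept factors,
#' fit by maximum likelihood (default) or REML. Used for the phenology and
#' migration-timing trend analyses (e.g. timing ~ year with herd unit as a
#' random intercept). Conditional R-squared follows the variance-partition
#' definition: `(var_fixed + sum sigma2_k) / (var_fixed + sum sigma2_k +
#' sigma2_resid)`, with `var_fixed` the variance of the fixed-effect
#' predictions.
#'
#' @param data a data frame.
#' @param response response column name.
#' @param fixed character vector of fixed-effect column names (an intercept
#'   is always included; may be empty for an intercept-only model).
#' @param random character vector (length 1--2) of grouping-factor column
#'   names, each entering as a random intercept.
#' @param reml use REML instead of ML.
#' @return an object of class `lmm_fit`: `fixed` (tibble of coefficients
#'   with SEs and Wald z), `var_components` (per-factor variances and the
#'   residual variance), `loglik`, `conditional_r2`, `marginal_r2`,
#'   `n_obs`, `n_groups`, `singular`, and the underlying `lme4` fit.
#' @export
fit_lmm <- function(data, response, fixed = character(), random, reml = FALSE) {
  stopifnot(length(random) >= 1, length(random) <= 2)
  miss <- setdiff(c(response, fixed, random), names(data))
  if (length(miss)) {
    stop("columns not in data: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (r in random) {
    if (length(unique(data[[r]])) < 2) {
      stop("random factor ", r, " has fewer than 2 levels", call. = FALSE)
    }
  }
  rhs <- paste(
    c(if (length(fixed)) fixed else "1", sprintf("(1 | %s)", random)),
    collapse = " + "
  )
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = data, REML = reml)
  ))

  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  fixed_tbl <- tibble::tibble(
    term = names(fe), estimate = unname(fe), std.error = unname(se),
    statistic = unname(fe / se),
    p.value = 2 * stats::pnorm(-abs(unname(fe / se)))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  ran_var <- stats::setNames(
    vc$vcov[vc$grp != "Residual"],
    vc$grp[vc$grp != "Residual"]
  )
  resid_var <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(drop(stats::model.matrix(fit) %*% fe))
  denom <- var_fixed + sum(ran_var) + resid_var
  structure(
    list(
      fixed = fixed_tbl,
      var_components = c(ran_var, residual = resid_var),
      loglik = as.numeric(stats::logLik(fit)),
      conditional_r2 = (var_fixed + sum(ran_var)) / denom,
      marginal_r2 = var_fixed / denom,
      n_obs = stats::nobs(fit),
      n_groups = vapply(lme4::ngrps(fit), as.integer, integer(1)),
      singular = lme4::isSingular(fit),
      reml = reml,
      model = fit
    ),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> %d obs, groups: %s; conditional R2 %.3f%s\n",
    x$n_obs,
    paste(names(x$n_groups), x$n_groups, sep = "=", collapse = ", "),
    x$conditional_r2,
    if (x$singular) " [singular]" else ""
  ))
  print(x$fixed)
  invisible(x)
}

#' @export
tidy.lmm_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    return(x$fixed)
  }
  tibble::tibble(
    term = names(x$var_components),
    estimate = unname(x$var_components)
  )
}

#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    conditional_r2 = x$conditional_r2,
    marginal_r2 = x$marginal_r2,
    nobs = x$n_obs,
    singular = x$singular
  )
}

#' Herd-year phenology and migration timing summaries
#'
#' Aggregates pixel-level green-up and snowmelt dates to herd-year means and
#' standard deviations, the snowmelt-to-green-up lag, and -- for herd units
#' with at least `min_individuals` tracked in at least `min_years` years --
#' the proportion of migrations whose midpoint preceded the herd-year mean
#' green-up date.
#'
#' @param phenology tibble with `herd_unit`, `year`, and per-pixel
#'   `greenup_doy`, `snowmelt_doy`.
#' @param strategies classification table with `herd_unit`, `year`,
#'   `animal_id`, `class`, `theta`.
#' @param min_individuals,min_years the herd-unit filter applied to the
#'   migration-vs-green-up comparison.
#' @return list with `herd_years` (one row per herd-year: timing means,
#'   SDs, `lag_days`) and `migration` (per filtered herd-year: `n_migrants`,
#'   `prop_before_greenup`, and overall attribute rows).
#' @export
timing_summaries <- function(phenology, strategies = NULL,
                             min_individuals = 3, min_years = 5) {
  herd_years <- phenology |>
    dplyr::group_by(.data$herd_unit, .data$year) |>
    dplyr::summarise(
      mean_greenup = mean(.data$greenup_doy, na.rm = TRUE),
      sd_greenup = stats::sd(.data$greenup_doy, na.rm = TRUE),
      mean_snowmelt = mean(.data$snowmelt_doy, na.rm = TRUE),
      sd_snowmelt = stats::sd(.data$snowmelt_doy, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sd_greenup = dplyr::coalesce(.data$sd_greenup, 0),
      sd_snowmelt = dplyr::coalesce(.data$sd_snowmelt, 0),
      lag_days = .data$mean_greenup - .data$mean_snowmelt
    )
  if (is.null(strategies)) {
    return(list(herd_years = herd_years, migration = NULL))
  }
  eligible_herds <- strategies |>
    dplyr::group_by(.data$herd_unit, .data$year) |>
    dplyr::summarise(n_ind = dplyr::n_distinct(.data$animal_id), .groups = "drop") |>
    dplyr::group_by(.data$herd_unit) |>
    dplyr::summarise(
      n_years_ok = sum(.data$n_ind >= min_individuals),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_years_ok >= min_years)
  migration <- strategies |>
    dplyr::filter(
      .data$class == "migrant",
      .data$herd_unit %in% eligible_herds$herd_unit
    ) |>
    dplyr::inner_join(herd_years, by = c("herd_unit", "year")) |>
    dplyr::group_by(.data$herd_unit, .data$year) |>
    dplyr::summarise(
      n_migrants = dplyr::n(),
      prop_before_greenup = mean(.data$theta < .data$mean_greenup),
      .groups = "drop"
    )
  list(herd_years = herd_years, migration = migration)
}
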