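#' Conditional logistic regression for matched step-selection strata
#'
#' Maximises the stratified conditional log-likelihood
#' `sum_s [beta . x_used - log sum_j exp(beta . x_j)]` by Newton--Raphson
#' with the analytic gradient and Hessian (the likelihood is concave), with
#' step-halving on overshoot. Model-based variance is the inverse observed
#' information; the robust variance is the sandwich estimator clustered by
#' individual. Each stratum holds one used endpoint (`case == 1`) and its
#' available alternatives (`case == 0`).
#'
#' Perfect separation (a covariate ranking the used step above every
#' alternative in all strata) makes the likelihood maximum escape to
#' infinity; a diverging coefficient norm is detected and reported via
#' `converged = FALSE` and `separation = TRUE`.
#'
#' @param data long stratum table with columns `stratum_id`, `case`, the
#'   covariates, and (for the robust variance) `animal_id`.
#' @param covariates character vector of covariate column names.
#' @param cluster column name for the robust-variance clusters (default
#'   `"animal_id"`; falls back to stratum-level clusters if absent).
#' @param max_iter,reltol Newton iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param beta_max largest absolute coefficient (on the working, typically
#'   z-scored, scale) beyond which separation is declared.
#' @return an object of class `clogit_fit`: `beta`, `se_model`,
#'   `se_robust`, `vcov_model`, `vcov_robust`, `loglik`, `loglik_null`,
#'   `qic`, `n_strata`, `n_individuals`, `iterations`, `converged`,
#'   `separation`.
#' @export
fit_clogit <- function(data, covariates, cluster = "animal_id",
                       max_iter = 50, reltol = 1e-10, beta_max = 30) {
  stopifnot(all(c("stratum_id", "case") %in% names(data)))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("covariates not in data: ", paste(missing_cov, collapse = ", "),
      call. = FALSE
    )
  }
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing covariate values; drop incomplete strata first", call. = FALSE)
  stratum <- as.integer(factor(data$stratum_id))
  case <- data$case
  used_per <- tapply(case, stratum, sum)
  if (any(used_per != 1)) {
    stop("every stratum must contain exactly one used (case == 1) row",
      call. = FALSE
    )
  }
  S <- max(stratum)
  p <- ncol(X)
  used <- which(case == 1)

  # identification lives in the within-stratum contrasts
  Xc <- X - rowsum(X, stratum)[stratum, , drop = FALSE] / tabulate(stratum)[stratum]
  r <- qr(Xc)$rank
  if (r == 0) {
    # no within-stratum information at all: the likelihood is flat at the
    # uniform-choice value and beta = 0 is the (non-unique) maximiser
    ll0 <- -sum(log(tabulate(stratum)))
    nap <- matrix(NA_real_, p, p, dimnames = list(covariates, covariates))
    return(structure(
      list(
        beta = stats::setNames(rep(0, p), covariates),
        se_model = stats::setNames(rep(NA_real_, p), covariates),
        se_robust = stats::setNames(rep(NA_real_, p), covariates),
        vcov_model = nap, vcov_robust = nap,
        loglik = ll0, loglik_null = ll0, info = nap,
        n_strata = S, n_obs = nrow(X),
        n_individuals = if (cluster %in% names(data)) {
          length(unique(data[[cluster]]))
        } else {
          S
        },
        covariates = covariates, iterations = 0L,
        converged = TRUE, separation = FALSE, grad_norm = 0,
        qic = NA_real_
      ),
      class = "clogit_fit"
    ))
  }
  if (r < p) {
    stop("design is rank deficient within strata", call. = FALSE)
  }

  loglik_parts <- function(beta) {
    eta <- drop(X %*% beta)
    smax <- as.numeric(tapply(eta, stratum, max))
    w <- exp(eta - smax[stratum])
    denom <- drop(rowsum(w, stratum))
    pr <- w / denom[stratum]
    ll <- sum(eta[used]) - sum(log(denom) + smax)
    mu <- rowsum(pr * X, stratum) # S x p, per-stratum weighted mean
    grad <- colSums(X[used, , drop = FALSE]) - colSums(mu)
    A <- crossprod(X, pr * X) # sum_j p_j x_j x_j'
    info <- A - crossprod(mu) # observed information (positive semidefinite)
    list(ll = ll, grad = grad, info = info, mu = mu, pr = pr)
  }

  beta <- rep(0, p)
  parts <- loglik_parts(beta)
  ll <- parts$ll
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(parts$info, parts$grad), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      parts_new <- loglik_parts(beta_new)
      if (is.finite(parts_new$ll) && parts_new$ll >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    if (!is.finite(parts_new$ll)) break
    improved <- parts_new$ll - ll
    beta <- beta_new
    parts <- parts_new
    ll <- parts$ll
    if (max(abs(beta)) > beta_max) {
      separation <- TRUE
      break
    }
    if (abs(improved) < reltol * (abs(ll) + reltol)) {
      converged <- TRUE
      break
    }
  }
  # a likelihood driven to (numerical) zero with a runaway coefficient is
  # separation even if the flat plateau tripped the convergence test
  if (max(abs(beta)) > beta_max) separation <- TRUE

  vcov_model <- tryCatch(solve(parts$info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(vcov_model) <- list(covariates, covariates)

  # cluster-robust sandwich: per-stratum score x_used - mu_s, summed by cluster
  ou <- used[order(stratum[used])] # align used rows with stratum-level order
  scores <- X[ou, , drop = FALSE] - parts$mu
  if (!is.null(cluster) && cluster %in% names(data)) {
    cl <- data[[cluster]][ou]
  } else {
    cl <- seq_len(S)
  }
  G <- rowsum(scores, cl)
  n_cl <- nrow(G)
  # CR1 finite-cluster correction, the standard degrees-of-freedom
  # adjustment for sandwich estimators with modest cluster counts
  meat <- crossprod(G) * if (n_cl > 1) n_cl / (n_cl - 1) else 1
  vcov_robust <- vcov_model %*% meat %*% vcov_model
  dimnames(vcov_robust) <- dimnames(vcov_model)

  names(beta) <- covariates
  fit <- structure(
    list(
      beta = beta,
      se_model = sqrt(diag(vcov_model)),
      se_robust = sqrt(diag(vcov_robust)),
      vcov_model = vcov_model, vcov_robust = vcov_robust,
      loglik = ll, loglik_null = -sum(log(tabulate(stratum))),
      info = parts$info,
      n_strata = S, n_obs = nrow(X),
      n_individuals = length(unique(cl)),
      covariates = covariates,
      iterations = iter, converged = converged && !separation,
      separation = separation,
      grad_norm = sqrt(sum(parts$grad^2))
    ),
    class = "clogit_fit"
  )
  fit$qic <- tryCatch(qic(fit), error = function(e) NA_real_)
  fit
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf(
    "<clogit_fit> %d strata, %d individuals, loglik %.2f, QIC %.2f%s\n",
    x$n_strata, x$n_individuals, x$loglik, x$qic,
    if (x$separation) " [SEPARATION]" else if (!x$converged) " [NOT CONVERGED]" else ""
  ))
  print(tidy.clogit_fit(x), n = length(x$beta))
  invisible(x)
}

#' Quasi-likelihood information criterion for a conditional-logistic fit
#'
#' `QIC = -2 loglik + 2 trace(I_model V_robust)` where `I_model` is the
#' observed information (inverse model-based variance). When the robust and
#' model-based variances agree the penalty reduces to `2p` and QIC equals
#' AIC.
#'
#' @param fit a [fit_clogit()] result.
#' @return the QIC value.
#' @export
qic <- function(fit) {
  if (anyNA(fit$vcov_model)) {
    stop("model variance is not invertible; cannot compute QIC", call. = FALSE)
  }
  imod <- solve(fit$vcov_model)
  -2 * fit$loglik + 2 * sum(diag(imod %*% fit$vcov_robust))
}

#' Select analysis windows around migration events
#'
#' Migrants contribute the 21 days centred on their fitted migration
#' midpoint `theta`. Residents contribute the 21 days centred on the mean
#' `theta` of migrants in their herd unit and year; residents in herd-years
#' with no detected migrants are excluded.
#'
#' @param strategies classification table from [classify_migration()] with
#'   `animal_id`, `year`, `class`, `theta`, `herd_unit`.
#' @param fixes fix table with `animal_id`, `year`, `doy` columns.
#' @return the windowed fixes joined with `class` and window bounds;
#'   excluded residents are absent.
#' @export
select_analysis_windows <- function(strategies, fixes) {
  stopifnot("herd_unit" %in% names(strategies))
  if (!"year" %in% names(fixes)) fixes$year <- 1L
  herd_mean <- strategies |>
    dplyr::filter(.data$class == "migrant") |>
    dplyr::group_by(.data$herd_unit, .data$year) |>
    dplyr::summarise(herd_theta = mean(.data$theta), .groups = "drop")
  centres <- strategies |>
    dplyr::left_join(herd_mean, by = c("herd_unit", "year")) |>
    dplyr::mutate(
      centre = dplyr::if_else(.data$class == "migrant", .data$theta, .data$herd_theta)
    ) |>
    dplyr::filter(!is.na(.data$centre)) |>
    dplyr::select(dplyr::all_of(c("animal_id", "year", "class", "centre")))
  fixes |>
    dplyr::inner_join(centres, by = c("animal_id", "year")) |>
    dplyr::filter(
      .data$doy >= .data$centre - 10.5,
      .data$doy <= .data$centre + 10.5
    )
}

#' Compare the overall model against nested covariate blocks
#'
#' Fits the model with every covariate and the nested models restricted to
#' single blocks (classically terrain, weather, snow, forage), returning the
#' QIC table sorted ascending with differences from the best model.
#'
#' @param data stratum table as for [fit_clogit()].
#' @param groupings named list of covariate-name vectors, one per nested
#'   model; the overall model uses their union.
#' @param cluster robust-variance cluster column.
#' @return a tibble `label`, `qic`, `delta_qic`, `n_covariates` sorted by
#'   QIC, with attribute `fits` holding the underlying `clogit_fit`s.
#' @export
compare_nested <- function(data, groupings, cluster = "animal_id") {
  stopifnot(length(groupings) >= 1, !is.null(names(groupings)))
  models <- c(list(overall = unique(unlist(groupings))), groupings)
  fits <- vector("list", length(models))
  names(fits) <- names(models)
  for (lb in names(models)) {
    f <- tryCatch(
      fit_clogit(data, models[[lb]], cluster = cluster),
      error = function(e) NULL
    )
    if (is.null(f) || !f$converged) {
      stop("model fit failed for block: ", lb, call. = FALSE)
    }
    fits[[lb]] <- f
  }
  tab <- tibble::tibble(
    label = names(fits),
    qic = unname(vapply(fits, function(f) f$qic, numeric(1))),
    n_covariates = unname(vapply(models, length, integer(1)))
  ) |>
    dplyr::arrange(.data$qic) |>
    dplyr::mutate(delta_qic = .data$qic - .data$qic[1])
  attr(tab, "fits") <- fits
  tab
}

#' Fit per-group step-selection models
#'
#' Independent conditional-logistic fits on population subsets (classically
#' females, males, residents, migrants, fast and slow migrants); groups
#' smaller than `min_strata` strata are skipped with a warning.
#'
#' @param data stratum table with a `group`ing column.
#' @param covariates covariate names.
#' @param group_col name of the grouping column.
#' @param min_strata minimum strata for a group to be fit.
#' @param cluster robust-variance cluster column.
#' @return named list of `clogit_fit`s (skipped groups absent); the tidy
#'   summary reports both raw and exponentiated coefficients via
#'   [tidy.clogit_fit()].
#' @export
fit_group_models <- function(data, covariates, group_col = "group",
                             min_strata = 100, cluster = "animal_id") {
  stopifnot(group_col %in% names(data))
  out <- list()
  for (g in unique(data[[group_col]])) {
    sub <- data[data[[group_col]] == g, , drop = FALSE]
    ns <- length(unique(sub$stratum_id))
    if (ns < min_strata) {
      warning("group ", g, " skipped: only ", ns, " strata")
      next
    }
    out[[as.character(g)]] <- fit_clogit(sub, covariates, cluster = cluster)
  }
  out
}

#' Used-step rank cross-validation
#'
#' Repeated fivefold cross-validation at the individual level: for each
#' repetition, individuals are partitioned into folds; the model is fit on
#' four folds and scored on the held-out strata by ranking each used step's
#' predicted selection weight `exp(beta . x)` among its stratum (rank 1 =
#' lowest). The fold score is the Spearman correlation between rank class
#' and the observed frequency of used steps in that class -- near 1 under
#' strong correctly-specified selection, near 0 under no selection. Falls
#' back to stratum-level folds (with a warning) when there are fewer
#' individuals than folds.
#'
#' @param data stratum table as for [fit_clogit()].
#' @param covariates covariate names.
#' @param folds,reps folds per repetition and number of repetitions.
#' @param seed integer seed for the fold draws.
#' @param cluster robust-variance cluster column (also the folding unit).
#' @return an object of class `issa_cv`: tibble of per-fold scores plus
#'   `mean` and `sd` attributes; `glance()` returns the summary.
#' @export
cross_validate <- function(data, covariates, folds = 5, reps = 100,
                           seed = 1L, cluster = "animal_id") {
  set.seed(seed)
  ids <- unique(data[[cluster]])
  unit_col <- cluster
  if (length(ids) < folds) {
    warning("fewer individuals than folds: falling back to stratum-level folding")
    unit_col <- "stratum_id"
    ids <- unique(data$stratum_id)
  }
  n_strata_tot <- length(unique(data$stratum_id))
  if (n_strata_tot < folds) stop("need at least `folds` strata", call. = FALSE)

  res <- vector("list", reps)
  for (r in seq_len(reps)) {
    fold_of <- sample(rep_len(seq_len(folds), length(ids)))
    names(fold_of) <- as.character(ids)
    scores <- numeric(folds)
    for (k in seq_len(folds)) {
      test_units <- names(fold_of)[fold_of == k]
      is_test <- as.character(data[[unit_col]]) %in% test_units
      train <- data[!is_test, , drop = FALSE]
      test <- data[is_test, , drop = FALSE]
      if (length(unique(train$stratum_id)) < 2 || nrow(test) == 0) {
        scores[k] <- NA_real_
        next
      }
      fit <- fit_clogit(train, covariates, cluster = cluster)
      eta <- drop(as.matrix(test[, covariates, drop = FALSE]) %*% fit$beta)
      rk <- stats::ave(eta, test$stratum_id, FUN = function(v) rank(v, ties.method = "average"))
      used_ranks <- rk[test$case == 1]
      n_alt <- max(table(test$stratum_id))
      freq <- tabulate(round(used_ranks), nbins = n_alt)
      scores[k] <- suppressWarnings(
        stats::cor(seq_len(n_alt), freq, method = "spearman")
      )
    }
    res[[r]] <- tibble::tibble(rep = r, fold = seq_len(folds), score = scores)
  }
  out <- dplyr::bind_rows(res)
  structure(out,
    class = c("issa_cv", class(out)),
    mean = mean(out$score, na.rm = TRUE),
    sd = stats::sd(out$score, na.rm = TRUE)
  )
}

#' @export
print.issa_cv <- function(x, ...) {
  cat(sprintf(
    "<issa_cv> %d scores: mean %.3f, sd %.3f\n",
    sum(is.finite(x$score)), attr(x, "mean"), attr(x, "sd")
  ))
  invisible(x)
}

#' @export
glance.issa_cv <- function(x, ...) {
  tibble::tibble(
    mean_score = attr(x, "mean"),
    sd_score = attr(x, "sd"),
    n_scores = sum(is.finite(x$score))
  )
}
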