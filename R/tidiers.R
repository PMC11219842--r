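#' Tidy a conditional-logistic fit
#'
#' @param x a `clogit_fit`.
#' @param robust use the cluster-robust standard errors (default) or the
#'   model-based ones. Robust (CR1) inference uses t critical values with
#'   `n_individuals - 1` degrees of freedom, the standard few-cluster
#'   recommendation; model-based inference uses the normal reference.
#' @param exponentiate add `exp.estimate` (relative selection strength).
#' @param conf.level Wald confidence level.
#' @param ... unused.
#' @return a tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high` and (optionally) `exp.estimate`.
#' @export
tidy.clogit_fit <- function(x, robust = TRUE, exponentiate = FALSE,
                            conf.level = 0.95, ...) {
  se <- if (robust) x$se_robust else x$se_model
  z <- x$beta / se
  a <- 1 - (1 - conf.level) / 2
  if (robust && is.finite(x$n_individuals) && x$n_individuals > 1) {
    df <- x$n_individuals - 1
    q <- stats::qt(a, df)
    pv <- 2 * stats::pt(-abs(unname(z)), df)
  } else {
    q <- stats::qnorm(a)
    pv <- 2 * stats::pnorm(-abs(unname(z)))
  }
  out <- tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(z),
    p.value = pv,
    conf.low = unname(x$beta - q * se),
    conf.high = unname(x$beta + q * se)
  )
  if (exponentiate) out$exp.estimate <- exp(out$estimate)
  out
}

#' @export
glance.clogit_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    logLik_null = x$loglik_null,
    qic = x$qic,
    n_strata = x$n_strata,
    n_individuals = x$n_individuals,
    nobs = x$n_obs,
    iterations = x$iterations,
    converged = x$converged,
    separation = x$separation
  )
}

#' Coefficient forest plot for a step-selection fit
#'
#' Point estimates with Wald intervals on the relative-selection-strength
#' (exponentiated) scale, one row per covariate.
#'
#' @param object a `clogit_fit`.
#' @param robust use robust standard errors.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.clogit_fit <- function(object, robust = TRUE, ...) {
  td <- tidy.clogit_fit(object, robust = robust)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = exp(.data$estimate), y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = exp(.data$conf.low), xmax = exp(.data$conf.high)),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Relative selection strength (exp(coefficient))",
      y = NULL
    )
}

#' @export
tidy.dlog_fit <- function(x, ...) {
  tibble::tibble(
    term = c("xmidS", "scalS", "xmidA", "scalA"),
    estimate = c(x$xmidS, x$scalS, x$xmidA, x$scalA)
  )
}

#' @export
glance.dlog_fit <- function(x, ...) {
  tibble::tibble(
    rmse = x$rmse, converged = x$converged, at_bound = x$at_bound,
    kind = x$kind, nobs = length(x$times)
  )
}

#' Fitted phenology curve over the observations
#'
#' @param object a `dlog_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dlog_fit <- function(object, ...) {
  obs <- tibble::tibble(t = object$times, value = object$values)
  tt <- seq(min(obs$t), max(obs$t), length.out = 400)
  cur <- tibble::tibble(t = tt, value = predict.dlog_fit(object, tt))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = cur, colour = "forestgreen") +
    ggplot2::labs(
      x = if (object$kind == "fsc") "Snow-year day" else "Day of year",
      y = if (object$kind == "fsc") "Fractional snow cover (%)" else "Rescaled NDVI"
    )
}

#' @export
tidy.nsd_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma0", "delta", "theta", "phi", "theta2", "phi2"),
    estimate = c(x$gamma0, x$delta, x$theta, x$phi, x$theta2, x$phi2)
  )
}

#' @export
glance.nsd_fit <- function(x, ...) {
  tibble::tibble(
    model_class = x$model_class, criterion = x$criterion,
    rss = x$rss, nobs = x$n, converged = x$converged
  )
}

#' Elevation profile with the three candidate migration curves
#'
#' @param object the list returned by [fit_elevation_models()].
#' @param day,elevation the data the models were fit to.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_migration_fit <- function(object, day, elevation, ...) {
  obs <- tibble::tibble(day = day, elevation = elevation)
  tt <- seq(min(day), max(day), length.out = 400)
  curve_of <- function(f) {
    if (!f$converged) {
      return(NULL)
    }
    v <- rep(f$gamma0, length(tt))
    if (f$model_class != "resident") {
      v <- v + f$delta / (1 + exp((f$theta - tt) / f$phi))
      if (!is.na(f$theta2)) {
        v <- v - f$delta / (1 + exp((f$theta2 - tt) / f$phi2))
      }
    }
    tibble::tibble(day = tt, elevation = v, model = f$model_class)
  }
  curves <- dplyr::bind_rows(lapply(object, curve_of))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$day, y = .data$elevation)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(colour = .data$model), linewidth = 0.8
    ) +
    ggplot2::labs(x = "Day of year", y = "Elevation (m)", colour = "Model")
}

#' Distribution of cross-validation scores
#'
#' @param object an `issa_cv`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.issa_cv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(
      xintercept = attr(object, "mean"),
      colour = "firebrick", linetype = "dashed"
    ) +
    ggplot2::labs(x = "Fold Spearman score", y = "Count")
}

#' Read and write GPS fix tables
#'
#' Plain-CSV exchange format for fixes: `animal_id`, `timestamp`
#' (ISO-8601 UTC), `x`, `y` in a shared projected metric CRS, plus optional
#' `herd_unit` and `sex` columns.
#'
#' @param path CSV file path.
#' @param fixes a fix tibble.
#' @return `read_fixes()` returns a tibble sorted by animal and time;
#'   `write_fixes()` returns `path` invisibly.
#' @export
read_fixes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("fix table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  # accept both "YYYY-mm-dd HH:MM:SS" and ISO-8601 "YYYY-mm-ddTHH:MM:SSZ"
  ts <- sub("Z$", "", gsub("T", " ", df$timestamp))
  df$timestamp <- as.POSIXct(ts, tz = "UTC")
  tibble::as_tibble(df) |>
    dplyr::arrange(.data$animal_id, .data$timestamp)
}

#' @rdname read_fixes
#' @export
write_fixes <- function(fixes, path) {
  out <- as.data.frame(fixes)
  if ("timestamp" %in% names(out)) {
    out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
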