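#' Double-logistic seasonal curve
#'
#' The land-surface phenology model used throughout the package for both
#' NDVI and fractional snow cover:
#' `1/(1 + exp((xmidS - t)/scalS)) - 1/(1 + exp((xmidA - t)/scalA))`.
#' `xmidS` and `xmidA` are the ordinal days of the rising (green-up / snow
#' accumulation) and falling (senescence / snowmelt) inflection points;
#' `scalS` and `scalA` are their timescales in days. The curve tends to 0 at
#' both ends of the season and approaches 1 on the plateau between
#' well-separated inflections.
#'
#' @param t time (day ordinal); vectorised, as are the parameters.
#' @param xmidS,scalS,xmidA,scalA curve parameters; `scalS`, `scalA` > 0.
#' @return numeric value(s) of the curve.
#' @examples
#' double_logistic_value(175, xmidS = 100, scalS = 5, xmidA = 250, scalA = 10)
#' @export
double_logistic_value <- function(t, xmidS, scalS, xmidA, scalA) {
  1 / (1 + exp((xmidS - t) / scalS)) - 1 / (1 + exp((xmidA - t) / scalA))
}

#' Rescale an NDVI series to its own annual unit range
#'
#' Negative raw values are raised to 0, then the series is linearly mapped so
#' its 2.5th percentile becomes 0 and its 97.5th percentile becomes 1
#' (linear-interpolation quantiles), clipping to `[0, 1]`.
#'
#' @param values raw NDVI values (unitless, within `[-1, 1]`).
#' @return list with `values` (rescaled), `lo`, `hi` (the percentile bounds
#'   on the raw scale, after the negative-floor step).
#' @export
rescale_series <- function(values) {
  if (length(values) < 8) {
    stop("need at least 8 observations to rescale", call. = FALSE)
  }
  v <- pmax(values, 0)
  lo <- vm_quantile(v, 0.025)
  hi <- vm_quantile(v, 0.975)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop("constant series: rescaling percentiles coincide", call. = FALSE)
  }
  list(values = pmin(pmax((v - lo) / (hi - lo), 0), 1), lo = lo, hi = hi)
}

#' Moving-median smoother
#'
#' Centred moving median of odd width; windows shrink symmetrically at the
#' endpoints (the first/last points use however much of the window fits).
#'
#' @param values numeric vector.
#' @param width odd window width (>= 1); `1` is the identity.
#' @return smoothed numeric vector of the same length.
#' @examples
#' smooth_median(c(0, 10, 0, 10, 0))
#' @export
smooth_median <- function(values, width = 3) {
  if (width %% 2 != 1 || width < 1) {
    stop("`width` must be an odd positive integer", call. = FALSE)
  }
  if (width == 1 || length(values) <= 1) {
    return(values)
  }
  h <- (width - 1) / 2
  n <- length(values)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    stats::median(values[lo:hi])
  }, numeric(1))
}

#' Fit the double-logistic phenology model to one pixel series
#'
#' Bounded nonlinear least squares (Levenberg--Marquardt) of the
#' double-logistic curve. NDVI series are fit on the rescaled `[0, 1]`
#' interval (amplitude 1); FSC series are fit on their native `[0, 100]`
#' percent interval (amplitude 100). Initial inflection days come from the
#' extreme first differences of the series; `scal` parameters start at
#' 5 days and are bounded to `[0.5, 60]` days, and inflection days are
#' bounded to the observed time span. A failed optimisation or a series
#' without both a rise and a fall yields `converged = FALSE` (never an
#' exception); parameters pinned at their bounds are flagged `at_bound`.
#'
#' @param times day ordinals (strictly increasing): calendar day-of-year for
#'   NDVI, snow-year day for FSC.
#' @param values series values, same length; rescaled `[0, 1]` NDVI or raw
#'   `[0, 100]` FSC.
#' @param kind `"ndvi"` or `"fsc"` (sets the curve amplitude).
#' @param lo,hi optional raw-scale bounds carried over from
#'   [rescale_series()] so predictions can be mapped back to the raw index.
#' @return An object of class `dlog_fit`: a list with `xmidS`, `scalS`,
#'   `xmidA`, `scalA`, `amplitude`, `lo`, `hi`, `rmse`, `converged`,
#'   `at_bound`, `kind`, and the data.
#' @export
fit_double_logistic <- function(times, values, kind = c("ndvi", "fsc"),
                                lo = NA_real_, hi = NA_real_) {
  kind <- match.arg(kind)
  failed <- function(msg) {
    structure(
      list(
        xmidS = NA_real_, scalS = NA_real_, xmidA = NA_real_, scalA = NA_real_,
        amplitude = if (kind == "fsc") 100 else 1, lo = lo, hi = hi,
        rmse = NA_real_, converged = FALSE, at_bound = FALSE,
        kind = kind, times = times, values = values, note = msg
      ),
      class = "dlog_fit"
    )
  }
  if (length(times) < 8 || length(values) != length(times)) {
    return(failed("too few points"))
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    return(failed("constant series"))
  }

  amp <- if (kind == "fsc") 100 else 1
  # locate candidate inflections on a denoised copy of the series so a
  # single noisy jump cannot hijack the starting values
  swidth <- min(max(3, 2 * floor(length(values) / 16) + 1), 11)
  sm <- smooth_median(values, swidth)
  d1 <- diff(sm) / diff(times)
  mids <- (times[-1] + times[-length(times)]) / 2
  s0 <- mids[which.max(d1)]
  a0 <- mids[which.min(d1)]
  if (a0 <= s0) { # fall precedes rise in the data: still try, re-ordered start
    tmp <- s0
    s0 <- min(s0, a0)
    a0 <- max(tmp, a0) + 1
  }
  # half-amplitude crossings as an independent second candidate
  half <- amp / 2
  up <- which(sm[-1] >= half & sm[-length(sm)] < half)
  dn <- which(sm[-1] < half & sm[-length(sm)] >= half)
  s1 <- if (length(up)) mids[up[1]] else s0
  a1 <- if (length(dn)) mids[dn[length(dn)]] else a0

  lower <- c(xmidS = min(times), scalS = 0.5, xmidA = min(times), scalA = 0.5)
  upper <- c(xmidS = max(times), scalS = 60, xmidA = max(times), scalA = 60)
  clamp <- function(v, i) min(max(v, lower[i]), upper[i])
  starts <- unique(list(
    c(xmidS = clamp(s0, 1), scalS = 5, xmidA = clamp(a0, 3), scalA = 5),
    c(xmidS = clamp(s1, 1), scalS = 5, xmidA = clamp(a1, 3), scalA = 5)
  ))

  fit <- NULL
  best_rss <- Inf
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        values ~ amp * (1 / (1 + exp((xmidS - times) / scalS)) -
          1 / (1 + exp((xmidA - times) / scalA))),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(cand)) {
      rss <- sum(stats::resid(cand)^2)
      if (rss < best_rss) {
        best_rss <- rss
        fit <- cand
      }
    }
  }
  if (is.null(fit)) {
    return(failed("optimizer failed"))
  }
  cf <- stats::coef(fit)
  tol <- 1e-6
  at_bound <- any(cf <= lower + tol) || any(cf >= upper - tol)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  converged <- is.finite(rmse) && cf[["xmidS"]] < cf[["xmidA"]] && !at_bound

  structure(
    list(
      xmidS = cf[["xmidS"]], scalS = cf[["scalS"]],
      xmidA = cf[["xmidA"]], scalA = cf[["scalA"]],
      amplitude = amp, lo = lo, hi = hi, rmse = rmse,
      converged = converged, at_bound = at_bound,
      kind = kind, times = times, values = values, note = NA_character_
    ),
    class = "dlog_fit"
  )
}

#' @export
print.dlog_fit <- function(x, ...) {
  cat(sprintf(
    "<dlog_fit %s> xmidS %.2f (scalS %.2f), xmidA %.2f (scalA %.2f), rmse %.4g%s\n",
    x$kind, x$xmidS, x$scalS, x$xmidA, x$scalA, x$rmse,
    if (!x$converged) " [NOT CONVERGED]" else ""
  ))
  invisible(x)
}

#' Predict from a fitted double-logistic curve
#'
#' @param object a `dlog_fit`.
#' @param t day ordinals (defaults to the fitted times).
#' @param ... unused.
#' @return predicted values on the fitted scale.
#' @export
predict.dlog_fit <- function(object, t = object$times, ...) {
  object$amplitude * double_logistic_value(
    t, object$xmidS, object$scalS, object$xmidA, object$scalA
  )
}

#' Fit phenology curves for a table of pixel series
#'
#' Applies the standard per-pixel chain: for NDVI, percentile rescaling of
#' the raw series, moving-median smoothing (width 3) of the rescaled series,
#' then the double-logistic fit; for FSC, a direct fit of the raw `[0, 100]`
#' series on the snow-day axis. Pixels whose fit fails keep a row with `converged =
#' FALSE` and missing parameters (their covariates propagate as missing
#' downstream).
#'
#' @param series a data frame with columns `pixel` (id), `time`, `value`.
#' @param kind `"ndvi"` or `"fsc"`.
#' @param smooth_width moving-median width applied to NDVI (odd; `1`
#'   disables).
#' @return a tibble with one row per pixel: `pixel`, `xmidS`, `scalS`,
#'   `xmidA`, `scalA`, `lo`, `hi`, `rmse`, `converged`.
#' @export
fit_phenology <- function(series, kind = c("ndvi", "fsc"), smooth_width = 3) {
  kind <- match.arg(kind)
  stopifnot(all(c("pixel", "time", "value") %in% names(series)))
  series |>
    dplyr::group_by(.data$pixel) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      f <- tryCatch(
        {
          if (kind == "ndvi") {
            rs <- rescale_series(df$value)
            sm <- smooth_median(rs$values, smooth_width)
            fit_double_logistic(df$time, sm,
              kind = "ndvi",
              lo = rs$lo, hi = rs$hi
            )
          } else {
            fit_double_logistic(df$time, df$value, kind = "fsc")
          }
        },
        error = function(e) NULL
      )
      if (is.null(f)) {
        return(tibble::tibble(
          xmidS = NA_real_, scalS = NA_real_, xmidA = NA_real_,
          scalA = NA_real_, lo = NA_real_, hi = NA_real_,
          rmse = NA_real_, converged = FALSE
        ))
      }
      tibble::tibble(
        xmidS = f$xmidS, scalS = f$scalS, xmidA = f$xmidA, scalA = f$scalA,
        lo = f$lo, hi = f$hi, rmse = f$rmse, converged = f$converged
      )
    }) |>
    dplyr::ungroup()
}

#' Phenology-derived covariates at a date
#'
#' Combines a pixel's NDVI fit and FSC fit into the per-date covariates:
#' green-up day (`xmidS` of the NDVI curve, calendar day-of-year), snowmelt
#' day (`xmidA` of the FSC curve, converted back from the snow-year axis),
#' relative NDVI (the curve prediction clipped to `[0, 1]`), absolute NDVI
#' (the prediction mapped back through the `lo`/`hi` rescaling bounds), and
#' signed days since each event (negative before it).
#'
#' @param ndvi_fit one-row data frame (or list) with NDVI-fit fields
#'   `xmidS`, `scalS`, `xmidA`, `scalA`, `lo`, `hi`, `converged`.
#' @param fsc_fit one-row data frame (or list) with FSC-fit fields `xmidA`
#'   and `converged` (snow-day axis).
#' @param doy calendar day-of-year of interest (vectorised).
#' @return a tibble with columns `doy`, `greenup_doy`, `snowmelt_doy`,
#'   `rel_ndvi`, `abs_ndvi`, `days_since_greenup`, `days_since_snowmelt`.
#'   Unconverged fits yield `NA` covariates.
#' @export
phenology_metrics <- function(ndvi_fit, fsc_fit, doy) {
  nd <- as.list(ndvi_fit)
  fs <- as.list(fsc_fit)
  n <- length(doy)
  out <- tibble::tibble(
    doy = doy,
    greenup_doy = NA_real_, snowmelt_doy = NA_real_,
    rel_ndvi = NA_real_, abs_ndvi = NA_real_,
    days_since_greenup = NA_real_, days_since_snowmelt = NA_real_
  )
  if (isTRUE(nd$converged)) {
    rel <- pmin(pmax(double_logistic_value(
      doy, nd$xmidS, nd$scalS, nd$xmidA, nd$scalA
    ), 0), 1)
    out$greenup_doy <- rep(nd$xmidS, n)
    out$rel_ndvi <- rel
    if (is.finite(nd$lo) && is.finite(nd$hi)) {
      out$abs_ndvi <- nd$lo + rel * (nd$hi - nd$lo)
    }
    out$days_since_greenup <- doy - nd$xmidS
  }
  if (isTRUE(fs$converged)) {
    melt_doy <- snowday_to_doy(fs$xmidA)
    out$snowmelt_doy <- rep(melt_doy, n)
    out$days_since_snowmelt <- doy - melt_doy
  }
  out
}
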