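#' Slope and aspect by the 4-neighbour rule
#'
#' Central differences over the rook-move neighbours:
#' `dz/dx = (E - W) / (2 cell)`, `dz/dy = (N - S) / (2 cell)`; border cells
#' use replicated edges (one-sided differences over the same 2-cell span).
#' Slope is `atan(||grad z||)` in degrees. Aspect is the compass bearing of
#' the downslope direction, degrees clockwise from north; it is undefined on
#' flat cells (`NA`), whose cosine-transformed aspect is set to the neutral
#' value 0 so that north-facing slopes score +1 and south-facing slopes -1.
#'
#' @param dem a [raster_grid()] of elevations (m) with at least 2 rows and
#'   2 columns.
#' @return list of [raster_grid()]s: `slope` (degrees, in `[0, 90]`),
#'   `aspect` (degrees from north, `NA` on flats), `cos_aspect`
#'   (`[-1, 1]`).
#' @examples
#' dem <- raster_grid(outer(1:5, 1:5, function(i, j) 10 * j), cellsize = 100)
#' slope_aspect(dem)$slope$values[3, 3] # atan(0.1) in degrees
#' @export
slope_aspect <- function(dem) {
  z <- dem$values
  nr <- nrow(z)
  nc <- ncol(z)
  if (nr < 2 || nc < 2) {
    stop("slope/aspect needs at least a 2 x 2 grid", call. = FALSE)
  }
  cs <- dem$cellsize
  # rook-move central differences; borders fall back to one-sided
  # differences over a single cell so planar surfaces stay exact
  east <- z[, c(2:nc, nc), drop = FALSE]
  west <- z[, c(1, 1:(nc - 1)), drop = FALSE]
  north <- z[c(2:nr, nr), , drop = FALSE]
  south <- z[c(1, 1:(nr - 1)), , drop = FALSE]
  span_x <- matrix(2 * cs, nr, nc)
  span_x[, c(1, nc)] <- cs
  span_y <- matrix(2 * cs, nr, nc)
  span_y[c(1, nr), ] <- cs
  dzdx <- (east - west) / span_x
  dzdy <- (north - south) / span_y

  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # downslope direction = -gradient; bearing clockwise from north
  asp <- atan2(-dzdx, -dzdy) * 180 / pi
  asp <- (asp + 360) %% 360
  flat <- dzdx == 0 & dzdy == 0
  asp[flat] <- NA_real_
  cosasp <- cos(asp * pi / 180)
  cosasp[flat] <- 0

  g <- function(v) raster_grid(v, dem$xmin, dem$ymin, cs)
  list(slope = g(slope), aspect = g(asp), cos_aspect = g(cosasp))
}

#' Escape-terrain mask
#'
#' Terrain steep enough that bighorn sheep are relatively safe from
#' predators, classified by a slope threshold (boundary inclusive).
#'
#' @param slope a [raster_grid()] of slopes in degrees.
#' @param threshold_deg slope threshold (degrees), default 30.
#' @return a logical [raster_grid()].
#' @export
escape_terrain <- function(slope, threshold_deg = 30) {
  g <- slope
  g$values <- slope$values >= threshold_deg
  g
}

#' Exact Euclidean distance transform of a mask
#'
#' Distance (m) from every cell centre to the nearest `TRUE` cell centre,
#' computed with the exact two-pass separable algorithm (per-column 1-d
#' squared distances, then per-row lower envelopes of parabolas). Zero on
#' `TRUE` cells. An empty mask yields `Inf` everywhere with a warning.
#'
#' @param mask a logical [raster_grid()].
#' @return a numeric [raster_grid()] of distances in metres.
#' @examples
#' m <- raster_grid(matrix(FALSE, 5, 5), cellsize = 30)
#' m$values[1, 1] <- TRUE
#' distance_to_mask(m)$values[4, 5] # 3-4-5 triangle: 150 m
#' @export
distance_to_mask <- function(mask) {
  v <- mask$values
  if (!is.logical(v)) {
    stop("`mask` must be a logical raster_grid", call. = FALSE)
  }
  if (!any(v)) {
    warning("empty mask: all distances are infinite")
    out <- mask
    out$values <- matrix(Inf, nrow(v), ncol(v))
    return(out)
  }
  nr <- nrow(v)
  nc <- ncol(v)
  INF <- 1e15
  # pass 1: per column, squared distance (in cells) to nearest TRUE in-column
  d <- matrix(INF, nr, nc)
  for (j in seq_len(nc)) {
    rows <- which(v[, j])
    if (length(rows)) {
      d[, j] <- (vapply(seq_len(nr), function(i) min(abs(i - rows)), numeric(1)))^2
    }
  }
  # pass 2: per row, 1-d squared EDT across columns (lower envelope)
  for (i in seq_len(nr)) {
    d[i, ] <- edt_1d(d[i, ], INF)
  }
  out <- mask
  out$values <- sqrt(d) * mask$cellsize
  out
}

# Felzenszwalb-Huttenlocher 1-d squared distance transform of function f
edt_1d <- function(f, INF) {
  n <- length(f)
  d <- numeric(n)
  vtx <- integer(n) # parabola vertices
  z <- numeric(n + 1) # envelope breakpoints
  k <- 1L
  vtx[1] <- 1L
  z[1] <- -INF
  z[2] <- INF
  for (q in 2:n) {
    repeat {
      p <- vtx[k]
      s <- ((f[q] + q^2) - (f[p] + p^2)) / (2 * q - 2 * p)
      if (s <= z[k] && k > 1L) {
        k <- k - 1L
      } else {
        break
      }
    }
    k <- k + 1L
    vtx[k] <- q
    z[k] <- s
    z[k + 1] <- INF
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < q) k <- k + 1L
    p <- vtx[k]
    d[q] <- (q - p)^2 + f[p]
  }
  d
}

#' Static terrain covariate bundle
#'
#' Convenience wrapper computing the full static covariate set from a DEM:
#' slope, aspect, cosine aspect, the escape-terrain mask and the distance to
#' escape terrain.
#'
#' @param dem a [raster_grid()] of elevations (m).
#' @param escape_threshold_deg slope threshold (degrees) defining escape
#'   terrain.
#' @return named list of [raster_grid()]s: `elevation`, `slope`, `aspect`,
#'   `cos_aspect`, `escape`, `dist_escape`.
#' @export
terrain_covariates <- function(dem, escape_threshold_deg = 30) {
  sa <- slope_aspect(dem)
  esc <- escape_terrain(sa$slope, escape_threshold_deg)
  list(
    elevation = dem,
    slope = sa$slope,
    aspect = sa$aspect,
    cos_aspect = sa$cos_aspect,
    escape = esc,
    dist_escape = distance_to_mask(esc)
  )
}

#' Distance to dense snowpack on a given day
#'
#' Thresholds the daily fractional-snow-cover layer into a snow mask
#' (default: FSC >= 50 percent counts as snow) and returns the distance
#' transform. Days with no snow anywhere return `Inf` distances (flagged by
#' [distance_to_mask()]'s warning).
#'
#' @param fsc_stack daily FSC [raster_stack()] (percent, snow-day axis).
#' @param snowday snow-year day of interest.
#' @param threshold FSC percent at and above which a cell counts as snow.
#' @return a [raster_grid()] of distances (m).
#' @export
distance_to_snow <- function(fsc_stack, snowday, threshold = 50) {
  layer <- rs_layer(fsc_stack, snowday)
  layer$values <- layer$values >= threshold
  distance_to_mask(layer)
}
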