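#' Matrix-backed georeferenced grid
#'
#' A `raster_grid` is a minimal container for a single-band gridded field on a
#' uniform, square-celled, projected coordinate system: a numeric matrix plus
#' an origin and a cell size in metres. Row index increases northward (row 1 is
#' the southernmost row), column index increases eastward, and all distances
#' are Euclidean in metres -- there is no geodesy.
#'
#' @param values numeric matrix (rows = south to north, cols = west to east).
#' @param xmin,ymin coordinates of the grid's lower-left corner (metres).
#' @param cellsize cell edge length (metres), strictly positive.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:12, 3, 4), cellsize = 100)
#' rg_extract(g, x = 150, y = 250)
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 1) {
  values <- as.matrix(values)
  if (!is.numeric(values) && !is.logical(values)) {
    stop("`values` must be a numeric or logical matrix", call. = FALSE)
  }
  if (nrow(values) < 1 || ncol(values) < 1) {
    stop("grid must have at least one row and one column", call. = FALSE)
  }
  if (!is.finite(cellsize) || cellsize <= 0) {
    stop("`cellsize` must be a positive number", call. = FALSE)
  }
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<raster_grid> %d x %d cells, cell %g m, origin (%g, %g)\n",
    nrow(v), ncol(v), x$cellsize, x$xmin, x$ymin
  ))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  values: [%g, %g]\n", min(fin), max(fin)))
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell-centre coordinates of a grid
#'
#' @param grid a [raster_grid()].
#' @return `rg_xcoords()`/`rg_ycoords()` return the vectors of column / row
#'   centre coordinates; `rg_extent()` returns `c(xmin, xmax, ymin, ymax)` of
#'   the outer cell edges.
#' @export
rg_xcoords <- function(grid) {
  grid$xmin + (seq_len(ncol(grid$values)) - 0.5) * grid$cellsize
}

#' @rdname rg_xcoords
#' @export
rg_ycoords <- function(grid) {
  grid$ymin + (seq_len(nrow(grid$values)) - 0.5) * grid$cellsize
}

#' @rdname rg_xcoords
#' @export
rg_extent <- function(grid) {
  c(
    xmin = grid$xmin,
    xmax = grid$xmin + ncol(grid$values) * grid$cellsize,
    ymin = grid$ymin,
    ymax = grid$ymin + nrow(grid$values) * grid$cellsize
  )
}

#' Locate points on a grid
#'
#' Maps point coordinates to the (row, col) of the cell containing them.
#' Points outside the grid extent get `NA` indices.
#'
#' @param grid a [raster_grid()].
#' @param x,y point coordinates (metres), recycled to a common length.
#' @return integer matrix with columns `row` and `col`.
#' @export
rg_cell_index <- function(grid, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  col <- floor((x - grid$xmin) / grid$cellsize) + 1
  row <- floor((y - grid$ymin) / grid$cellsize) + 1
  # points exactly on the top/right edge belong to the last cell
  col[x == grid$xmin + ncol(grid$values) * grid$cellsize] <- ncol(grid$values)
  row[y == grid$ymin + nrow(grid$values) * grid$cellsize] <- nrow(grid$values)
  bad <- col < 1 | col > ncol(grid$values) | row < 1 | row > nrow(grid$values)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Nearest-cell extraction
#'
#' @inheritParams rg_cell_index
#' @return numeric vector of cell values; `NA` outside the extent.
#' @export
rg_extract <- function(grid, x, y) {
  idx <- rg_cell_index(grid, x, y)
  out <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx[, 1])
  out[ok] <- grid$values[idx[ok, , drop = FALSE]]
  out
}

#' Test whether points fall inside a grid's extent
#'
#' @inheritParams rg_cell_index
#' @return logical vector.
#' @export
rg_inside <- function(grid, x, y) {
  ext <- rg_extent(grid)
  x >= ext["xmin"] & x <= ext["xmax"] & y >= ext["ymin"] & y <= ext["ymax"]
}

#' @export
as_tibble.raster_grid <- function(x, ...) {
  xs <- rep(rg_xcoords(x), each = nrow(x$values))
  ys <- rep(rg_ycoords(x), times = ncol(x$values))
  vals <- as.vector(x$values)
  tibble::tibble(x = xs, y = ys, value = vals)
}

#' Raster grid heat map
#'
#' @param object a [raster_grid()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- as_tibble.raster_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)")
}

#' Read and write Esri ASCII grids
#'
#' Plain-text single-band grid exchange (`.asc`). The on-disk format stores
#' rows north-to-south; they are flipped to this package's south-to-north
#' row order on read and back on write.
#'
#' @param grid a [raster_grid()].
#' @param path file path.
#' @param nodata value written for `NA` cells.
#' @return `read_ascii_grid()` returns a [raster_grid()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[!is.finite(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- val("ncols")
  nrows <- val("nrows")
  nodata <- val("NODATA_value")
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- matrix(as.numeric(unlist(body)), nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m[rev(seq_len(nrows)), , drop = FALSE],
    xmin = val("xllcorner"), ymin = val("yllcorner"), cellsize = val("cellsize")
  )
}

#' Time-indexed stack of grids
#'
#' A `raster_stack` shares one grid geometry across layers indexed by an
#' integer time axis (`time_basis` records whether indices are calendar
#' day-of-year or snow-year days, see [doy_to_snowday()]).
#'
#' @param template a [raster_grid()] supplying the geometry.
#' @param times integer layer times, strictly increasing.
#' @param values 3-d array `[rows, cols, length(times)]`.
#' @param time_basis `"doy"` or `"snowday"`.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(template, times, values, time_basis = c("doy", "snowday")) {
  time_basis <- match.arg(time_basis)
  stopifnot(
    inherits(template, "raster_grid"),
    length(dim(values)) == 3,
    dim(values)[3] == length(times),
    all(dim(values)[1:2] == dim(template$values)),
    !is.unsorted(times, strictly = TRUE)
  )
  structure(
    list(
      template = template, times = as.integer(times),
      values = values, time_basis = time_basis
    ),
    class = "raster_stack"
  )
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf(
    "<raster_stack> %d x %d cells, %d layers (%s %d..%d)\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
    x$time_basis, min(x$times), max(x$times)
  ))
  invisible(x)
}

#' Extract one layer of a stack as a grid
#'
#' @param stack a [raster_stack()].
#' @param time layer time; the nearest available layer at or before `time`
#'   is used when `exact = FALSE` (NDVI-style composites), otherwise the
#'   time must match a layer exactly.
#' @param exact require an exact layer match.
#' @return a [raster_grid()].
#' @export
rs_layer <- function(stack, time, exact = FALSE) {
  i <- rs_layer_index(stack, time, exact)
  if (is.na(i)) stop("time ", time, " outside stack range", call. = FALSE)
  g <- stack$template
  g$values <- stack$values[, , i]
  g
}

rs_layer_index <- function(stack, time, exact = FALSE) {
  if (exact) {
    i <- match(time, stack$times)
  } else {
    # latest layer starting at or before `time` (composite convention)
    i <- findInterval(time, stack$times)
    i[i == 0] <- NA_integer_
  }
  i
}

#' Space-time extraction from a stack
#'
#' Nearest-cell extraction at each product's native grid; the layer is the
#' latest one starting at or before each requested time.
#'
#' @param stack a [raster_stack()].
#' @param x,y,time point coordinates and times (recycled to common length).
#' @return numeric vector; `NA` outside the spatial extent or before the
#'   first layer.
#' @export
rs_extract <- function(stack, x, y, time) {
  n <- max(length(x), length(y), length(time))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  time <- rep_len(time, n)
  idx <- rg_cell_index(stack$template, x, y)
  li <- rs_layer_index(stack, time)
  ok <- !is.na(idx[, 1]) & !is.na(li)
  out <- rep(NA_real_, n)
  if (any(ok)) {
    out[ok] <- stack$values[cbind(idx[ok, 1], idx[ok, 2], li[ok])]
  }
  out
}
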