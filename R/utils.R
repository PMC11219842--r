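#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Package-wide quantile convention: linear interpolation between order
# statistics (R default type 7). Used for the 2.5/97.5% rescale bounds and
# the 75th-percentile hot-day threshold.
vm_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7, na.rm = TRUE)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Snow-year day arithmetic
#'
#' Fractional-snow-cover series are analysed on a "snow year" running
#' 15 August to 14 August so each series starts and ends at a summertime
#' snow-free baseline. `snow_day()` converts calendar dates to the 1-based
#' day within their snow year (leap years handled by calendar arithmetic);
#' `snow_day_to_date()` inverts it. `doy_to_snowday()`/`snowday_to_doy()`
#' are the fixed 365-day versions used for synthetic nominal years.
#'
#' @param date a `Date` vector.
#' @return `snow_day()`: list with `day` (integer) and `snow_year` (the
#'   calendar year in which the snow year begins).
#' @examples
#' snow_day(as.Date("2020-08-15")) # day 1 of snow year 2020
#' @export
snow_day <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  origin <- as.Date(sprintf("%d-08-15", yr))
  before <- date < origin
  yr[before] <- yr[before] - 1L
  origin[before] <- as.Date(sprintf("%d-08-15", yr[before]))
  list(day = as.integer(date - origin) + 1L, snow_year = yr)
}

#' @rdname snow_day
#' @param day 1-based snow-year day.
#' @param snow_year calendar year in which the snow year begins (its
#'   15 August is day 1).
#' @export
snow_day_to_date <- function(day, snow_year) {
  as.Date(sprintf("%d-08-15", snow_year)) + (day - 1)
}

#' @rdname snow_day
#' @param doy calendar day-of-year in a nominal 365-day year.
#' @export
doy_to_snowday <- function(doy) {
  ifelse(doy >= 227, doy - 226, doy + 139)
}

#' @rdname snow_day
#' @param snowday snow-year day in a nominal 365-day year.
#' @export
snowday_to_doy <- function(snowday) {
  ifelse(snowday <= 139, snowday + 226, snowday - 139)
}
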