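## 365-day (no-leap) calendar helpers.  Synthetic climate is generated on a
## noleap calendar, the convention of most long climate-model runs; month
## boundaries below are therefore fixed.

.MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_END <- cumsum(.MONTH_DAYS)
.MONTH_START <- c(1L, .MONTH_END[-12L] + 1L)

#' No-leap calendar utilities
#'
#' `noleapCalendar()` expands a year range into (year, doy) pairs on the
#' 365-day calendar; `monthOfDoy()` maps a day of year to its month;
#' `warmSeasonMask()` flags the warm-season window in which labour losses
#' are accounted: June-September in the Northern Hemisphere, December-March
#' in the Southern Hemisphere.  Cells within one degree of the equator
#' follow the Northern-Hemisphere window by convention.
#'
#' @param startYear,endYear integer calendar years (inclusive).
#' @param doy integer day of year in 1..365.
#' @param lat numeric latitude in degrees (positive north).
#' @return `noleapCalendar()` a data.frame with columns `year` and `doy`;
#'   `monthOfDoy()` an integer month 1..12; `warmSeasonMask()` a logical
#'   matrix (length(lat) x length(doy)).
#' @examples
#' cal <- noleapCalendar(2000, 2001)
#' nrow(cal)  # 730
#' monthOfDoy(152)  # June 1st
#' @export
noleapCalendar <- function(startYear, endYear) {
  stopifnot(endYear >= startYear)
  years <- seq.int(startYear, endYear)
  data.frame(year = rep(as.integer(years), each = 365L),
             doy = rep(1:365, length(years)))
}

#' @rdname noleapCalendar
#' @export
monthOfDoy <- function(doy) {
  stopifnot(all(doy >= 1L & doy <= 365L))
  findInterval(doy, .MONTH_START)
}

#' @rdname noleapCalendar
#' @export
warmSeasonMask <- function(lat, doy) {
  month <- monthOfDoy(doy)
  nh <- month %in% 6:9          # June 1 - September 30
  sh <- month %in% c(12L, 1:3)  # December 1 - March 30/31
  north <- lat >= -1            # equatorial band follows the NH window
  out <- matrix(FALSE, length(lat), length(doy))
  if (any(north))
    out[north, ] <- matrix(nh, sum(north), length(doy), byrow = TRUE)
  if (any(!north))
    out[!north, ] <- matrix(sh, sum(!north), length(doy), byrow = TRUE)
  out
}
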