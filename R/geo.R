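# Geographic primitives: great-circle distance, isolation-date resolution,
# window eligibility.

# Mean Earth radius, km (IUGG R1).
.EARTH_RADIUS_KM <- 6371.0088

#' Validate geographic coordinates
#'
#' @param lat latitude in decimal degrees, in \[-90, 90\].
#' @param lon longitude in decimal degrees, in \[-180, 180\].
#' @return invisibly, a list with `lat` and `lon`.
#' @export
geo_point <- function(lat, lon) {
  stopifnot(is.numeric(lat), is.numeric(lon), length(lat) == length(lon))
  if (any(!is.na(lat) & (lat < -90 | lat > 90)))
    stop("latitude out of [-90, 90]")
  if (any(!is.na(lon) & (lon < -180 | lon > 180)))
    stop("longitude out of [-180, 180]")
  invisible(list(lat = lat, lon = lon))
}

#' Great-circle (haversine) distance
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorised over
#' point pairs.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance in kilometers.
#' @examples
#' great_circle_distance(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  geo_point(lat1, lon1); geo_point(lat2, lon2)
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Resolve an isolation record's anchor date
#'
#' Records with day precision anchor on the recorded date; month precision
#' defaults to the first of that month; year precision defaults to January 1
#' of that year.
#'
#' @param year,month,day integer date parts (`month`/`day` may be `NA`).
#' @param precision one of `"day"`, `"month"`, `"year"`.
#' @return a `Date` anchor.
#' @export
resolve_isolation_date <- function(year, month = NA, day = NA,
                                   precision = c("day", "month", "year")) {
  precision <- match.arg(precision)
  if (is.na(year)) stop("year is required")
  switch(precision,
    day = {
      if (is.na(month) || is.na(day))
        stop("day precision requires month and day")
      as.Date(sprintf("%04d-%02d-%02d", year, month, day))
    },
    month = {
      if (is.na(month)) stop("month precision requires month")
      as.Date(sprintf("%04d-%02d-01", year, month))
    },
    year = as.Date(sprintf("%04d-01-01", year))
  )
}

#' Analysis window specification
#'
#' Windows are centered on the anchor date: `floor(duration/2)` days before
#' the anchor, with total length `duration` days (3-month = 91 days,
#' one-year = 365, three-year = 1095).
#'
#' @param name one of `"three_month"`, `"one_year"`, `"three_year"`.
#' @param anchor anchor `Date` (the resolved isolation date).
#' @return a list with `name`, `duration`, `start`, `end` (inclusive dates).
#' @export
window_spec <- function(name = c("three_month", "one_year", "three_year"),
                        anchor) {
  name <- match.arg(name)
  duration <- c(three_month = 91L, one_year = 365L, three_year = 1095L)[[name]]
  anchor <- as.Date(anchor)
  start <- anchor - duration %/% 2L
  structure(list(name = name, duration = duration, anchor = anchor,
                 start = start, end = start + duration - 1L),
            class = "window_spec")
}

#' Window duration in days for a window name
#' @param name window name.
#' @return integer number of days.
#' @export
window_duration <- function(name) {
  c(three_month = 91L, one_year = 365L, three_year = 1095L)[[name]]
}

#' Strains eligible for an analysis window
#'
#' Date-precision requirements grow with window length: the 3-month window
#' needs the exact day of isolation, the one-year window day or month, and
#' the three-year window accepts year-only records. Records without a
#' location are always excluded.
#'
#' @param records data.frame with columns `strain`, `lat`, `lon`, `year`,
#'   `month`, `day`, `date_precision` (one of day/month/year/none).
#' @param window window name.
#' @return the eligible subset of `records`.
#' @export
eligible_strains <- function(records,
                             window = c("three_month", "one_year",
                                        "three_year")) {
  window <- match.arg(window)
  ok_prec <- switch(window,
    three_month = "day",
    one_year = c("day", "month"),
    three_year = c("day", "month", "year"))
  keep <- records$date_precision %in% ok_prec &
    !is.na(records$lat) & !is.na(records$lon)
  records[keep, , drop = FALSE]
}

#' Resolve anchor dates for a set of records
#' @param records as in [eligible_strains()].
#' @return `Date` vector aligned with rows of `records`.
#' @export
resolve_anchor_dates <- function(records) {
  as.Date(vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (identical(r$date_precision, "none")) return(NA_real_)
    as.numeric(resolve_isolation_date(r$year, r$month, r$day,
                                      r$date_precision))
  }, numeric(1)), origin = "1970-01-01")
}
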