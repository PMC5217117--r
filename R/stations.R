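# Station quality control, nearest-station assignment, elevation providers,
# neighboring-station agreement.

.month_key <- function(d) format(as.Date(d), "%Y-%m")

.window_months <- function(window) {
  s <- as.Date(format(window$start, "%Y-%m-01"))
  e <- as.Date(format(window$end, "%Y-%m-01"))
  .month_key(seq(s, e, by = "month"))
}

#' Per-station monthly recording counts
#'
#' Counts observation rows (recordings of any type, regardless of parameter)
#' per station and calendar month. Used by station quality control.
#'
#' @param obs observation data.frame with `station_id` and `timestamp`.
#' @return a data.table with columns `station_id`, `month` ("YYYY-MM"), `n`.
#' @export
station_monthly_counts <- function(obs) {
  dt <- data.table::as.data.table(obs[, c("station_id", "timestamp")])
  dt[, month := .month_key(timestamp)]
  dt[, .(n = .N), by = .(station_id, month)]
}

#' Station quality control for a window
#'
#' A station passes for a given window iff every calendar month overlapping
#' the window has at least `min_per_month` recordings of any type at that
#' station. Months with no recordings at all fail. An empty series fails.
#'
#' @param timestamps recording timestamps (Date or POSIXct or ISO strings)
#'   for one station, or a monthly-count data.frame for one station with
#'   columns `month`, `n`.
#' @param window a [window_spec()].
#' @param min_per_month minimum recordings per month (default 10).
#' @return `TRUE` or `FALSE`.
#' @export
station_passes_qc <- function(timestamps, window, min_per_month = 10L) {
  months <- .window_months(window)
  if (is.data.frame(timestamps)) {
    counts <- setNames(timestamps$n, timestamps$month)
  } else {
    if (length(timestamps) == 0) return(FALSE)
    counts <- table(.month_key(timestamps))
  }
  got <- counts[months]
  got[is.na(got)] <- 0L
  all(got >= min_per_month)
}

.qc_lookup <- function(monthly_counts, station_ids, months,
                       min_per_month = 10L) {
  # matrix station x month of counts; absent combinations are zero
  mc <- monthly_counts[station_id %in% station_ids & month %in% months]
  m <- matrix(0L, length(station_ids), length(months),
              dimnames = list(station_ids, months))
  if (nrow(mc)) m[cbind(match(mc$station_id, station_ids),
                        match(mc$month, months))] <- mc$n
  rowSums(m < min_per_month) == 0L
}

#' Assign the nearest QC-passing station to each strain
#'
#' For each eligible strain, computes the window centered on its resolved
#' isolation date and returns the QC-passing station minimizing great-circle
#' distance. Ties are broken by lexicographic station id. Assignments are
#' computed independently per window, so a station too sparse for the
#' 3-month window can still serve the one- or three-year windows.
#'
#' @param records eligible isolation records (see [eligible_strains()]).
#' @param stations station catalog (`station_id`, `lat`, `lon`, `elevation`).
#' @param obs observation table, or precomputed [station_monthly_counts()].
#' @param window window name.
#' @param min_per_month QC threshold, recordings per month.
#' @return data.frame `strain`, `window`, `station_id`, `distance_km`,
#'   `anchor`; strains with no passing station are dropped with a warning.
#' @export
assign_nearest_station <- function(records, stations, obs,
                                   window = c("three_month", "one_year",
                                              "three_year"),
                                   min_per_month = 10L) {
  window <- match.arg(window)
  records <- eligible_strains(records, window)
  if (nrow(records) == 0)
    return(data.frame(strain = character(), window = character(),
                      station_id = character(), distance_km = numeric(),
                      anchor = as.Date(character())))
  mc <- if (data.table::is.data.table(obs) && "n" %in% names(obs)) obs
        else station_monthly_counts(obs)
  anchors <- resolve_anchor_dates(records)
  # station order by id for deterministic tie-breaks
  stations <- stations[order(stations$station_id), , drop = FALSE]
  out <- vector("list", nrow(records))
  dropped <- character()
  # cache QC verdicts per (window-month-set) since many strains share months
  qc_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(records))) {
    w <- window_spec(window, anchors[i])
    months <- .window_months(w)
    key <- paste(months, collapse = "|")
    pass <- qc_cache[[key]]
    if (is.null(pass)) {
      pass <- .qc_lookup(mc, stations$station_id, months, min_per_month)
      qc_cache[[key]] <- pass
    }
    if (!any(pass)) { dropped <- c(dropped, records$strain[i]); next }
    cand <- stations[pass, , drop = FALSE]
    d <- great_circle_distance(records$lat[i], records$lon[i],
                               cand$lat, cand$lon)
    j <- which.min(d)  # first index on ties = lexicographically smallest id
    out[[i]] <- data.frame(strain = records$strain[i], window = window,
                           station_id = cand$station_id[j],
                           distance_km = d[j], anchor = anchors[i])
  }
  if (length(dropped))
    warning(sprintf("no QC-passing station for %d strain(s) [%s]: %s",
                    length(dropped), window,
                    paste(dropped, collapse = ", ")))
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Elevation lookup through a pluggable provider
#'
#' @param lat,lon coordinates.
#' @param provider a function `(lat, lon) -> meters` returning `NA` outside
#'   its coverage; see [station_elevation_provider()] and
#'   [synthetic_elevation_provider()].
#' @return elevation in meters, `NA` where the provider has no coverage.
#' @export
elevation_of <- function(lat, lon, provider) {
  stopifnot(is.function(provider))
  provider(lat, lon)
}

#' Elevation provider from station elevations
#'
#' Inverse-distance-weighted (power 2) mean of the `k` nearest stations'
#' catalog elevations. Returns `NA` for points farther than `max_km` from
#' the nearest station (no coverage).
#'
#' @param stations station catalog.
#' @param k number of neighbors (default 6).
#' @param power inverse-distance exponent (default 2).
#' @param max_km coverage radius in km (default 2000).
#' @return a provider function for [elevation_of()].
#' @export
station_elevation_provider <- function(stations, k = 6L, power = 2,
                                       max_km = 2000) {
  force(stations); force(k); force(power); force(max_km)
  function(lat, lon) {
    vapply(seq_along(lat), function(i) {
      if (is.na(lat[i]) || is.na(lon[i])) return(NA_real_)
      d <- great_circle_distance(lat[i], lon[i], stations$lat, stations$lon)
      if (min(d) > max_km) return(NA_real_)
      o <- order(d)[seq_len(min(k, length(d)))]
      w <- 1 / pmax(d[o], 1e-6)^power
      sum(w * stations$elevation[o]) / sum(w)
    }, numeric(1))
  }
}

#' Rank-correlation agreement between two neighboring stations
#'
#' Aggregates both observation series to daily means for one parameter,
#' pairs them by date, and returns the Spearman correlation — the sanity
#' check that a strain's assigned station is representative of nearby
#' weather.
#'
#' @param series_a,series_b observation data.frames (`timestamp`, `param`,
#'   `value`).
#' @param parameter parameter code, e.g. `"temp"`.
#' @return Spearman rho.
#' @export
station_agreement <- function(series_a, series_b, parameter) {
  day_means <- function(s) {
    s <- s[s$param == parameter, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    dt <- data.table::as.data.table(s)
    dt[, date := as.Date(timestamp)]
    dt[, .(m = mean(value)), by = date]
  }
  a <- day_means(series_a); b <- day_means(series_b)
  if (is.null(a) || is.null(b)) stop("parameter absent from a series")
  ab <- merge(a, b, by = "date")
  if (nrow(ab) < 3) stop("fewer than 3 paired days")
  cor(ab$m.x, ab$m.y, method = "spearman")
}
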