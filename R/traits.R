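# Climate phenotypes: unit harmonization, daily aggregation, window
# summarization, coverage filtering, geographic traits.

# Parameter codes admitted for quantitative analysis (ISD-style short codes).
.QUANT_PARAMS <- c("temp", "rh", "wd", "ws", "ceil_hgt", "dew_point", "precip")

#' Harmonize raw observation records
#'
#' Converts raw records to analysis units and drops qualitative fields.
#' Precipitation, reported as a depth over a variable accumulation period,
#' is converted to a per-hour rate (`value / period_hours`, mm/hr) so that
#' averaging across stations with different reporting periods is meaningful.
#' Temperatures in tenths of a degree or Fahrenheit are converted to Celsius.
#' Records of qualitative parameters (anything outside the quantitative
#' code set) are removed, as are precipitation rows with a zero period
#' (warned).
#'
#' @param raw data.frame: `station_id`, `timestamp`, `param`, `value`,
#'   `unit`, and `period_hours` for precipitation rows.
#' @return harmonized observation data.frame (`station_id`, `timestamp`,
#'   `param`, `value`, `unit`).
#' @export
harmonize_units <- function(raw) {
  x <- raw[!is.na(raw$value) & raw$param %in% .QUANT_PARAMS, , drop = FALSE]
  if ("unit" %in% names(x)) {
    f <- x$unit %in% "degF"
    x$value[f] <- (x$value[f] - 32) * 5 / 9
    x$unit[f] <- "degC"
    t10 <- x$unit %in% "tenth_degC"
    x$value[t10] <- x$value[t10] / 10
    x$unit[t10] <- "degC"
  } else {
    x$unit <- NA_character_
  }
  p <- which(x$param == "precip")
  if (length(p)) {
    per <- if ("period_hours" %in% names(x)) x$period_hours[p] else rep(1, length(p))
    per[is.na(per)] <- 1
    bad <- per == 0
    if (any(bad)) {
      warning(sprintf("dropping %d precipitation record(s) with zero period",
                      sum(bad)))
      x <- x[-p[bad], , drop = FALSE]
      p <- which(x$param == "precip")
      per <- per[!bad]
    }
    x$value[p] <- x$value[p] / per
    x$unit[p] <- "mm_per_hr"
  }
  x$period_hours <- NULL
  rownames(x) <- NULL
  x
}

#' Daily aggregation of an observation series
#'
#' Per station, calendar day and parameter: mean, min, max and variance of
#' that day's recordings. Days with a single recording get variance 0; days
#' with no recordings are simply absent.
#'
#' @param obs harmonized observations (`station_id`, `timestamp`, `param`,
#'   `value`).
#' @return data.table: `station_id`, `date`, `param`, `daily_mean`,
#'   `daily_min`, `daily_max`, `daily_var`.
#' @export
daily_aggregate <- function(obs) {
  dt <- data.table::as.data.table(obs)
  dt[, date := as.Date(timestamp)]
  out <- dt[, .(daily_mean = mean(value),
                daily_min = min(value),
                daily_max = max(value),
                daily_var = if (.N > 1) var(value) else 0),
            by = .(station_id, date, param)]
  data.table::setorder(out, station_id, param, date)
  out
}

#' Summarize daily values over an analysis window
#'
#' The phenotypic value of a trait is the unweighted mean of in-window daily
#' means (two-stage averaging: recordings to days, days to window), never a
#' pooled mean over recordings. Companion statistics are the means of the
#' daily minima, maxima and variances.
#'
#' @param daily output of [daily_aggregate()] for one station.
#' @param window a [window_spec()].
#' @return data.frame `param`, `mean`, `min`, `max`, `var` (one row per
#'   parameter with at least one in-window day), or zero rows if none.
#' @export
window_summarize <- function(daily, window) {
  d <- daily[daily$date >= window$start & daily$date <= window$end, ,
             drop = FALSE]
  if (!nrow(d))
    return(data.frame(param = character(), mean = numeric(),
                      min = numeric(), max = numeric(), var = numeric()))
  dt <- data.table::as.data.table(d)
  as.data.frame(dt[, .(mean = mean(daily_mean), min = mean(daily_min),
                       max = mean(daily_max), var = mean(daily_var)),
                   by = param])
}

#' Geographic trait columns for isolation records
#'
#' latitude, longitude, their absolute values, and elevation through the
#' supplied provider. Records without a location get `NA`s.
#'
#' @param records isolation records.
#' @param elevation_provider provider for [elevation_of()]; `NULL` leaves
#'   elevation `NA`.
#' @return data.frame with rownames = strain ids.
#' @export
geographic_traits <- function(records, elevation_provider = NULL) {
  elev <- if (is.null(elevation_provider)) rep(NA_real_, nrow(records))
          else elevation_of(records$lat, records$lon, elevation_provider)
  out <- data.frame(latitude = records$lat, abslat = abs(records$lat),
                    longitude = records$lon, abslong = abs(records$lon),
                    elevation = elev)
  rownames(out) <- records$strain
  out
}

#' Build the strain-by-trait phenotype table for one window
#'
#' Runs the full phenotype construction: strain eligibility by date
#' precision, nearest QC-passing station assignment, windowed two-stage
#' aggregation of that station's observations, geographic traits, and the
#' coverage filter. Weather trait columns are named
#' `<param>_<stat>_<window>`.
#'
#' @param records isolation records.
#' @param stations station catalog.
#' @param obs harmonized observations.
#' @param window window name.
#' @param elevation_provider optional elevation provider.
#' @param coverage_threshold fraction of strains that must have a value for
#'   a trait column to be kept (strictly greater than; default 0.90).
#'   `NULL` skips the filter.
#' @param stats which daily statistics to emit (subset of mean/min/max/var).
#' @return data.frame of traits, one row per assigned strain; attribute
#'   `assignment` carries the station assignment table.
#' @export
build_trait_table <- function(records, stations, obs,
                              window = c("three_month", "one_year",
                                         "three_year"),
                              elevation_provider = NULL,
                              coverage_threshold = 0.90,
                              stats = c("mean", "min", "max", "var")) {
  window <- match.arg(window)
  stats <- match.arg(stats, several.ok = TRUE)
  asn <- assign_nearest_station(records, stations, obs, window)
  if (is.null(asn) || nrow(asn) == 0) stop("no strain could be assigned a station")
  daily <- daily_aggregate(obs)
  rows <- vector("list", nrow(asn))
  for (i in seq_len(nrow(asn))) {
    w <- window_spec(window, asn$anchor[i])
    sdaily <- daily[daily$station_id == asn$station_id[i], , drop = FALSE]
    ws <- window_summarize(sdaily, w)
    vals <- list()
    for (j in seq_len(nrow(ws)))
      for (s in stats)
        vals[[paste(ws$param[j], s, window, sep = "_")]] <- ws[[s]][j]
    rows[[i]] <- vals
  }
  cols <- unique(unlist(lapply(rows, names)))
  cols <- cols[order(match(sub("_.*", "", cols), .QUANT_PARAMS))]
  weather <- as.data.frame(lapply(cols, function(cn)
    vapply(rows, function(r) r[[cn]] %||% NA_real_, numeric(1))))
  names(weather) <- cols
  rownames(weather) <- asn$strain
  geo <- geographic_traits(records[match(asn$strain, records$strain), ,
                                   drop = FALSE], elevation_provider)
  tab <- cbind(geo, weather)
  if (!is.null(coverage_threshold))
    tab <- coverage_filter(tab, coverage_threshold)
  attr(tab, "assignment") <- asn
  tab
}

#' Drop trait columns with insufficient strain coverage
#'
#' Keeps only traits with values in strictly greater than
#' `threshold` of strains (default: >90%).
#'
#' @param table trait data.frame (strains as rows).
#' @param threshold coverage fraction.
#' @return filtered table.
#' @export
coverage_filter <- function(table, threshold = 0.90) {
  frac <- colMeans(!is.na(table))
  keep <- frac > threshold
  out <- table[, keep, drop = FALSE]
  attr(out, "assignment") <- attr(table, "assignment")
  out
}

#' Pairwise Spearman correlations between traits
#'
#' Pairwise-complete Spearman correlations; entries involving a constant
#' trait are `NA`.
#'
#' @param table trait data.frame.
#' @return correlation matrix.
#' @export
trait_correlations <- function(table) {
  m <- as.matrix(table)
  suppressWarnings(cor(m, method = "spearman",
                       use = "pairwise.complete.obs"))
}

#' Per-trait strain-level summaries
#'
#' Count, minimum, mean and maximum of each trait over strains with data —
#' the strain-level summaries reported alongside a trait table.
#'
#' @param table trait data.frame (strains as rows).
#' @return data.frame `trait`, `n`, `min`, `mean`, `max`.
#' @export
trait_summary <- function(table) {
  do.call(rbind, lapply(names(table), function(cn) {
    v <- table[[cn]][!is.na(table[[cn]])]
    data.frame(trait = cn, n = length(v),
               min = if (length(v)) min(v) else NA_real_,
               mean = if (length(v)) mean(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_)
  }))
}
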