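# Synthetic-world generator: structured genotypes, weather-station fields,
# isolation records with a plantable habitat-choice effect, and competition
# allele counts. Every generator is a pure function of (config, seed).

#' Configuration for the synthetic world
#'
#' @param n_strains number of wild strains/isotypes (>= 2).
#' @param n_subpops number of subpopulations.
#' @param fst Wright's fixation index controlling between-subpopulation
#'   allele-frequency divergence, in \[0, 1).
#' @param n_markers number of biallelic markers.
#' @param n_stations number of weather stations.
#' @param lat_range,lon_range coverage of the world, decimal degrees.
#' @param causal_marker_index optional 1-based index of the planted causal
#'   marker.
#' @param causal_effect_degC shift in isolation-site long-run temperature per
#'   alternative allele (habitat-choice effect), degrees C.
#' @param temp_pref_sd spread (sd, degrees C) of strain temperature
#'   preferences around the world mean.
#' @param window_days_missing_rate probability that a station-month is
#'   thinned below the QC threshold (exercises station QC).
#' @param date_precision_probs named probabilities for day/month/year
#'   isolation-date precision.
#' @param start_year first calendar year of the observation span.
#' @param span_years length of the observation span in years.
#' @param seed integer RNG seed.
#' @return validated config list of class `world_config`.
#' @export
world_config <- function(n_strains = 150L, n_subpops = 3L, fst = 0.2,
                         n_markers = 2000L, n_stations = 150L,
                         lat_range = c(-50, 50), lon_range = c(-120, 120),
                         causal_marker_index = NULL, causal_effect_degC = 0,
                         temp_pref_sd = 3,
                         window_days_missing_rate = 0.02,
                         date_precision_probs = c(day = 122, month = 16,
                                                  year = 7) / 145,
                         start_year = 2001L, span_years = 5L, seed = 1L) {
  stopifnot(n_strains >= 2, fst >= 0, fst < 1, n_subpops >= 1,
            n_markers >= 1, n_stations >= 1,
            window_days_missing_rate >= 0, window_days_missing_rate <= 1,
            abs(sum(date_precision_probs) - 1) < 1e-8)
  if (!is.null(causal_marker_index))
    stopifnot(causal_marker_index >= 1, causal_marker_index <= n_markers)
  structure(as.list(environment()), class = "world_config")
}

#' Climate field model for the synthetic world
#'
#' A deterministic temperature field — warm equator, linear cooling with
#' absolute latitude and elevation, hemisphere-phased seasonal sinusoid —
#' plus AR(1) daily weather noise; relative humidity declines linearly with
#' temperature, so the generated abs-latitude/temperature and
#' temperature/humidity correlations are negative by construction.
#'
#' @param equator_mean_temp long-run mean temperature at the equator and sea
#'   level, degrees C.
#' @param lapse_per_abslat_deg cooling per degree of absolute latitude,
#'   degrees C / degree.
#' @param elevation_lapse cooling per meter of elevation (default 0.0065).
#' @param seasonal_amplitude amplitude of the seasonal sinusoid, degrees C.
#' @param daily_noise_sd sd of daily AR(1) weather noise, degrees C.
#' @param ar1 AR(1) autocorrelation of daily noise.
#' @param rh_intercept,rh_slope_per_degC linear humidity-temperature
#'   relation (%, %/degC; slope negative).
#' @return a `climate_field` list.
#' @export
climate_field_model <- function(equator_mean_temp = 26,
                                lapse_per_abslat_deg = 0.45,
                                elevation_lapse = 0.0065,
                                seasonal_amplitude = 6,
                                daily_noise_sd = 2, ar1 = 0.7,
                                rh_intercept = 95,
                                rh_slope_per_degC = -1.3) {
  stopifnot(rh_slope_per_degC < 0, daily_noise_sd >= 0, ar1 >= 0, ar1 < 1)
  structure(as.list(environment()), class = "climate_field")
}

# Smooth deterministic elevation field (meters, >= 0).
.elevation_field <- function(lat, lon) {
  250 * (1 + sin(lon * pi / 60) * cos(lat * pi / 45))
}

# Long-run (deterministic) mean temperature of a site.
.long_run_temp <- function(lat, elev, climate) {
  climate$equator_mean_temp - climate$lapse_per_abslat_deg * abs(lat) -
    climate$elevation_lapse * elev
}

#' Generate structured biallelic genotypes
#'
#' Balding-Nichols population structure: per-marker ancestral frequencies
#' are Uniform(0.05, 0.95); each subpopulation draws its frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) (ancestral frequency exactly at F = 0);
#' strains are haploid-coded 0/1 (selfing isogenic isotypes). A planted
#' causal marker, if configured, gets an intermediate ancestral frequency
#' (Uniform(0.3, 0.7)) so the habitat-choice contrast is observable.
#'
#' Marker metadata (attribute `"markers"`) places markers uniformly on six
#' chromosomes with strictly increasing positions, assigns each to a
#' synthetic gene (two markers per gene) and a functional-impact class.
#'
#' @param config a [world_config()].
#' @return 0/1 matrix strains x markers with attributes `markers`
#'   (data.frame marker/chrom/pos/gene/impact) and `subpop`.
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, {
    n <- config$n_strains; m <- config$n_markers; f <- config$fst
    subpop <- sample(config$n_subpops, n, replace = TRUE)
    p_anc <- runif(m, 0.05, 0.95)
    ci <- config$causal_marker_index
    if (!is.null(ci)) p_anc[ci] <- runif(1, 0.3, 0.7)
    if (f == 0) {
      P <- matrix(p_anc, config$n_subpops, m, byrow = TRUE)
    } else {
      a <- p_anc * (1 - f) / f
      b <- (1 - p_anc) * (1 - f) / f
      P <- t(vapply(seq_len(config$n_subpops),
                    function(k) rbeta(m, a, b), numeric(m)))
    }
    G <- matrix(rbinom(n * m, 1L, P[subpop, ]), n, m)
    dimnames(G) <- list(sprintf("S%03d", seq_len(n)),
                        sprintf("M%05d", seq_len(m)))
    chroms <- c("I", "II", "III", "IV", "V", "X")
    chrom <- chroms[ceiling(seq_len(m) / ceiling(m / 6))]
    idx_in <- stats::ave(seq_len(m), chrom, FUN = seq_along)
    pos <- idx_in * 10000L  # 10 kb spacing, strictly increasing per chrom
    impact <- sample(c("moderate", "severe", "low"), m, replace = TRUE,
                     prob = c(0.4, 0.2, 0.4))
    if (!is.null(ci)) impact[ci] <- "moderate"
    markers <- data.frame(marker = colnames(G), chrom = chrom, pos = pos,
                          gene = paste0("gene_", chrom, "_",
                                        ceiling(idx_in / 2)),
                          impact = impact, stringsAsFactors = FALSE)
    attr(G, "markers") <- markers
    attr(G, "subpop") <- subpop
    G
  })
}

#' Generate the synthetic world
#'
#' Places stations uniformly over the configured lat/lon range with a
#' smooth elevation field, simulates daily observations (temperature,
#' relative humidity, dew point, wind, precipitation) over the span with a
#' hemisphere-phased seasonal sinusoid plus AR(1) noise, thins a configured
#' fraction of station-months below the QC threshold, and draws each
#' strain's isolation site by habitat choice: a strain's preferred
#' temperature is Normal(world mean, `temp_pref_sd`) shifted by
#' `causal_effect_degC` per alternative allele at the causal marker, and the
#' strain settles near the station whose long-run temperature best matches.
#'
#' @param config a [world_config()].
#' @param climate a [climate_field_model()].
#' @param genotypes optional genotype matrix from [generate_genotypes()]
#'   (generated from `config` when omitted).
#' @param params parameter codes to simulate (subset of
#'   temp/rh/dew_point/ws/wd/precip; fewer keeps large simulations fast).
#' @return list of class `synthetic_world`: `stations`, `obs`, `records`,
#'   `genotypes`, `annotations`, `truth`.
#' @export
generate_world <- function(config, climate = climate_field_model(),
                           genotypes = NULL,
                           params = c("temp", "rh", "dew_point", "ws", "wd",
                                      "precip")) {
  stopifnot(inherits(config, "world_config"), inherits(climate, "climate_field"))
  params <- match.arg(params, several.ok = TRUE)
  span_days <- as.integer(as.Date(sprintf("%d-01-01",
                                          config$start_year + config$span_years)) -
                          as.Date(sprintf("%d-01-01", config$start_year)))
  widest <- window_duration("three_year")
  if (span_days < widest + 2L)
    stop("observation span shorter than the widest analysis window")
  G <- genotypes %||% generate_genotypes(config)
  with_seed(config$seed + 1L, {
    ns <- config$n_stations
    st_lat <- runif(ns, config$lat_range[1], config$lat_range[2])
    st_lon <- runif(ns, config$lon_range[1], config$lon_range[2])
    st_elev <- .elevation_field(st_lat, st_lon)
    stations <- data.frame(station_id = sprintf("W%04d", seq_len(ns)),
                           lat = st_lat, lon = st_lon, elevation = st_elev,
                           stringsAsFactors = FALSE)
    dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
                 by = "day", length.out = span_days)
    doy <- as.integer(format(dates, "%j"))
    nd <- length(dates)
    t_base <- .long_run_temp(st_lat, st_elev, climate)
    phase <- ifelse(st_lat >= 0, 196, 15)  # mid-July / mid-January peak
    seas <- climate$seasonal_amplitude *
      cos(outer(doy, phase, function(d, p) 2 * pi * (d - p) / 365.25))
    # AR(1) noise, one column per station
    eps <- matrix(rnorm(nd * ns, sd = climate$daily_noise_sd *
                          sqrt(1 - climate$ar1^2)), nd, ns)
    noise <- apply(eps, 2, function(e)
      as.numeric(stats::filter(e, climate$ar1, method = "recursive")))
    temp <- sweep(seas + noise, 2, t_base, "+")
    obs_list <- list()
    sid <- rep(stations$station_id, each = nd)
    ts_all <- rep(dates, ns)
    if ("temp" %in% params)
      obs_list$temp <- data.frame(station_id = sid, timestamp = ts_all,
                                  param = "temp", value = as.numeric(temp),
                                  unit = "degC", period_hours = NA_real_)
    if ("rh" %in% params) {
      rh <- climate$rh_intercept + climate$rh_slope_per_degC * temp +
        matrix(rnorm(nd * ns, sd = 4), nd, ns)
      rh <- pmin(100, pmax(5, rh))
      obs_list$rh <- data.frame(station_id = sid, timestamp = ts_all,
                                param = "rh", value = as.numeric(rh),
                                unit = "%", period_hours = NA_real_)
    }
    if ("dew_point" %in% params) {
      rh_for_dp <- if (!is.null(obs_list$rh))
        matrix(obs_list$rh$value, nd, ns) else pmin(100, pmax(5,
        climate$rh_intercept + climate$rh_slope_per_degC * temp))
      dp <- temp - (100 - rh_for_dp) / 5
      obs_list$dew_point <- data.frame(station_id = sid, timestamp = ts_all,
                                       param = "dew_point",
                                       value = as.numeric(dp),
                                       unit = "degC",
                                       period_hours = NA_real_)
    }
    if ("ws" %in% params)
      obs_list$ws <- data.frame(station_id = sid, timestamp = ts_all,
                                param = "ws",
                                value = pmax(0, rnorm(nd * ns, 4, 2)),
                                unit = "m_per_s", period_hours = NA_real_)
    if ("wd" %in% params)
      obs_list$wd <- data.frame(station_id = sid, timestamp = ts_all,
                                param = "wd",
                                value = runif(nd * ns, 0, 360),
                                unit = "deg", period_hours = NA_real_)
    if ("precip" %in% params) {
      period <- sample(c(1, 3, 6, 12, 24), nd * ns, replace = TRUE)
      rate <- ifelse(runif(nd * ns) < 0.3, stats::rexp(nd * ns, 1), 0)
      obs_list$precip <- data.frame(station_id = sid, timestamp = ts_all,
                                    param = "precip",
                                    value = rate * period, unit = "mm",
                                    period_hours = period)
    }
    obs <- do.call(rbind, obs_list)
    rownames(obs) <- NULL
    # thin a fraction of station-months below the QC threshold
    if (config$window_days_missing_rate > 0) {
      mk <- .month_key(obs$timestamp)
      all_sm <- unique(paste(obs$station_id, mk, sep = "/"))
      thin <- all_sm[runif(length(all_sm)) < config$window_days_missing_rate]
      if (length(thin)) {
        key <- paste(obs$station_id, mk, sep = "/")
        drop <- key %in% thin
        # keep at most 0..9 recordings in a thinned month
        keep_n <- setNames(sample(0:9, length(thin), replace = TRUE), thin)
        idx <- which(drop)
        ord <- idx[order(key[idx], runif(length(idx)))]
        rl <- rle(key[ord])
        keep_first <- unlist(mapply(function(len, k) {
          kk <- min(len, keep_n[[k]])
          c(rep(TRUE, kk), rep(FALSE, len - kk))
        }, rl$lengths, rl$values, SIMPLIFY = FALSE))
        drop[ord] <- !keep_first
        obs <- obs[!drop, , drop = FALSE]
      }
    }
    # habitat choice: strain settles near the best-matching station
    n <- config$n_strains
    ci <- config$causal_marker_index
    g_causal <- if (is.null(ci)) rep(0L, n) else G[, ci]
    target <- rnorm(n, mean(t_base), config$temp_pref_sd) +
      config$causal_effect_degC * g_causal
    choice <- vapply(target, function(tt)
      which.min(abs(t_base - tt) + rnorm(ns, sd = 0.5)), integer(1))
    lat <- pmin(config$lat_range[2], pmax(config$lat_range[1],
                st_lat[choice] + rnorm(n, sd = 0.3)))
    lon <- pmin(config$lon_range[2], pmax(config$lon_range[1],
                st_lon[choice] + rnorm(n, sd = 0.3)))
    # isolation dates keep the widest centered window inside the span
    margin <- widest %/% 2 + 1L
    iso_date <- dates[sample(seq(margin, nd - margin), n, replace = TRUE)]
    prec <- sample(names(config$date_precision_probs), n, replace = TRUE,
                   prob = config$date_precision_probs)
    yr <- as.integer(format(iso_date, "%Y"))
    mo <- ifelse(prec == "year", NA_integer_,
                 as.integer(format(iso_date, "%m")))
    dy <- ifelse(prec == "day", as.integer(format(iso_date, "%d")),
                 NA_integer_)
    records <- data.frame(strain = rownames(G), lat = lat, lon = lon,
                          year = yr, month = mo, day = dy,
                          date_precision = prec, stringsAsFactors = FALSE)
    truth <- list(causal_marker = if (is.null(ci)) NULL else colnames(G)[ci],
                  causal_marker_index = ci,
                  causal_effect_degC = config$causal_effect_degC,
                  subpop = attr(G, "subpop"),
                  station_long_run_temp = t_base,
                  chosen_station = stations$station_id[choice],
                  target_temp = target, true_isolation_date = iso_date)
    structure(list(stations = stations, obs = obs, records = records,
                   genotypes = G, annotations = attr(G, "markers"),
                   truth = truth, config = config, climate = climate),
              class = "synthetic_world")
  })
}

#' Exact elevation provider for a synthetic world
#'
#' Returns the generator's own elevation field inside the configured
#' lat/lon range and `NA` outside it (missing coverage, never zero).
#'
#' @param world a `synthetic_world` (or a [world_config()]).
#' @return provider function for [elevation_of()].
#' @export
synthetic_elevation_provider <- function(world) {
  cfg <- if (inherits(world, "synthetic_world")) world$config else world
  function(lat, lon) {
    out <- .elevation_field(lat, lon)
    out[is.na(lat) | is.na(lon) |
          lat < cfg$lat_range[1] | lat > cfg$lat_range[2] |
          lon < cfg$lon_range[1] | lon > cfg$lon_range[2]] <- NA_real_
    out
  }
}

#' Simulate two-strain competition allele counts
#'
#' Deterministic logistic decay of the A-allele frequency,
#' `logit(p_t) = logit(p0) - t * log(w_rel)`, sampled with binomial droplet
#' noise at the listed culture transfers.
#'
#' @param p0 initial A-allele frequency (0 < p0 < 1).
#' @param w_rel relative fitness of the B strain per transfer (> 0; 1 is
#'   neutral).
#' @param transfers transfer indices at which counts are taken.
#' @param droplets droplets genotyped per sample (> 0).
#' @param replicates number of replicate populations.
#' @param seed RNG seed.
#' @param temperature label carried through to the output.
#' @return data.frame `temperature`, `replicate`, `transfer`, `count_A`,
#'   `count_B`.
#' @export
generate_competition_counts <- function(p0, w_rel, transfers = c(2, 4, 6),
                                        droplets = 10000L, replicates = 9L,
                                        seed = 1L, temperature = NA) {
  stopifnot(p0 > 0, p0 < 1, w_rel > 0)
  if (droplets <= 0) stop("droplets must be positive")
  with_seed(seed, {
    p_t <- plogis(qlogis(p0) - transfers * log(w_rel))
    out <- expand.grid(transfer = transfers,
                       replicate = seq_len(replicates))
    out$count_A <- rbinom(nrow(out), droplets,
                          p_t[match(out$transfer, transfers)])
    out$count_B <- droplets - out$count_A
    data.frame(temperature = temperature, replicate = out$replicate,
               transfer = out$transfer, count_A = out$count_A,
               count_B = out$count_B)
  })
}
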