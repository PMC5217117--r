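# Small in-code fixtures shared across the suite.

# Isolation records with the study's date-precision mix: 122 day-precision,
# 16 month-only, 7 year-only located records, plus 4 without usable data.
fixture_records_145 <- function() {
  n <- 149
  prec <- c(rep("day", 122), rep("month", 16), rep("year", 7),
            rep("none", 4))
  data.frame(
    strain = sprintf("ST%03d", seq_len(n)),
    lat = c(rep(45, 145), rep(NA, 4)),
    lon = rep(5, n),
    year = 2003L,
    month = ifelse(prec %in% c("day", "month"), 6L, NA_integer_),
    day = ifelse(prec == "day", 15L, NA_integer_),
    date_precision = prec, stringsAsFactors = FALSE)
}

# Dense daily observation series for one station over [from, to].
fixture_station_obs <- function(station_id, from, to, param = "temp",
                                per_day = 1L, value_fn = function(d) 15) {
  dates <- rep(seq(as.Date(from), as.Date(to), by = "day"), each = per_day)
  data.frame(station_id = station_id, timestamp = dates, param = param,
             value = vapply(dates, value_fn, numeric(1)), unit = "degC",
             stringsAsFactors = FALSE)
}

# A tiny fully-observed world for pipeline-level tests.
fixture_small_world <- function(seed = 1, n_strains = 60, n_markers = 300,
                                n_stations = 40, effect = 0, causal = NULL) {
  cfg <- world_config(n_strains = n_strains, n_markers = n_markers,
                      n_stations = n_stations,
                      causal_marker_index = causal,
                      causal_effect_degC = effect, seed = seed)
  generate_world(cfg, params = "temp")
}

# Hudson FST estimator (ratio of averages) for two subpopulations —
# independent brute-force oracle for the genotype generator.
hudson_fst <- function(G, subpop) {
  stopifnot(length(unique(subpop)) == 2)
  s <- sort(unique(subpop))
  g1 <- G[subpop == s[1], , drop = FALSE]
  g2 <- G[subpop == s[2], , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  p1 <- colMeans(g1); p2 <- colMeans(g2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
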