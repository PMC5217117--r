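# The synthetic-world generator: structure, planted effects, determinism.

test_that("generators are pure functions of (config, seed)", {
  cfg <- world_config(n_strains = 30, n_markers = 100, n_stations = 15,
                      span_years = 4, seed = 77)
  G1 <- generate_genotypes(cfg)
  G2 <- generate_genotypes(cfg)
  expect_identical(G1, G2)
  w1 <- generate_world(cfg, params = "temp")
  w2 <- generate_world(cfg, params = "temp")
  expect_identical(w1$obs, w2$obs)
  expect_identical(w1$records, w2$records)
  expect_identical(w1$stations, w2$stations)
  c1 <- generate_competition_counts(0.5, 1.5, seed = 3)
  c2 <- generate_competition_counts(0.5, 1.5, seed = 3)
  expect_identical(c1, c2)
})

test_that("Balding-Nichols structure: no divergence at fst = 0, Hudson FST
           recovers fst = 0.3", {
  cfg0 <- world_config(n_strains = 400, n_subpops = 2, fst = 0,
                       n_markers = 500, seed = 5)
  G0 <- generate_genotypes(cfg0)
  sp0 <- attr(G0, "subpop")
  diff0 <- mean(abs(colMeans(G0[sp0 == 1, ]) - colMeans(G0[sp0 == 2, ])))
  expect_lt(diff0, 0.08)

  cfg3 <- world_config(n_strains = 400, n_subpops = 2, fst = 0.3,
                       n_markers = 1000, seed = 6)
  G3 <- generate_genotypes(cfg3)
  sp3 <- attr(G3, "subpop")
  diff3 <- mean(abs(colMeans(G3[sp3 == 1, ]) - colMeans(G3[sp3 == 2, ])))
  expect_gt(diff3, diff0)
  expect_equal(hudson_fst(G3, sp3), 0.3, tolerance = 0.05 / 0.3)
})

test_that("marker metadata has six chromosomes with strictly increasing
           positions", {
  G <- generate_genotypes(world_config(n_strains = 10, n_markers = 120,
                                       seed = 2))
  mk <- attr(G, "markers")
  expect_setequal(unique(mk$chrom), c("I", "II", "III", "IV", "V", "X"))
  for (ch in unique(mk$chrom))
    expect_true(all(diff(mk$pos[mk$chrom == ch]) > 0))
})

test_that("habitat choice plants the configured temperature effect and a
           null effect stays null", {
  cfg5 <- world_config(n_strains = 150, n_markers = 200, n_stations = 100,
                       causal_marker_index = 50, causal_effect_degC = 5,
                       seed = 31)
  w5 <- generate_world(cfg5, params = "temp")
  g <- w5$genotypes[, 50]
  lt <- w5$truth$station_long_run_temp[
    match(w5$truth$chosen_station, w5$stations$station_id)]
  d <- mean(lt[g == 1]) - mean(lt[g == 0])
  se <- sqrt(var(lt[g == 1]) / sum(g == 1) + var(lt[g == 0]) / sum(g == 0))
  expect_lt(abs(d - 5), 3 * se)

  cfg0 <- world_config(n_strains = 150, n_markers = 200, n_stations = 100,
                       causal_marker_index = 50, causal_effect_degC = 0,
                       seed = 32)
  w0 <- generate_world(cfg0, params = "temp")
  g0 <- w0$genotypes[, 50]
  lt0 <- w0$truth$station_long_run_temp[
    match(w0$truth$chosen_station, w0$stations$station_id)]
  expect_lt(abs(cor(g0, lt0, method = "spearman")), 0.2)
})

test_that("date precisions are emitted in the configured proportions", {
  cfg <- world_config(n_strains = 400, n_markers = 20, n_stations = 20,
                      date_precision_probs = c(day = 0.5, month = 0.3,
                                               year = 0.2), seed = 8)
  w <- generate_world(cfg, params = "temp")
  pr <- table(w$records$date_precision) / 400
  expect_equal(as.numeric(pr[c("day", "month", "year")]),
               c(0.5, 0.3, 0.2), tolerance = 0.35)
  expect_true(all(is.na(w$records$day[w$records$date_precision == "month"])))
  expect_true(all(is.na(w$records$month[w$records$date_precision == "year"])))
})

test_that("generated abs-latitude is strongly anticorrelated with long-run
           temperature and humidity tracks temperature negatively", {
  cfg <- world_config(n_strains = 120, n_markers = 50, n_stations = 80,
                      seed = 14)
  w <- generate_world(cfg, params = c("temp", "rh"))
  lt <- w$truth$station_long_run_temp[
    match(w$truth$chosen_station, w$stations$station_id)]
  expect_lte(cor(abs(w$records$lat), lt, method = "spearman"), -0.5)

  dt <- data.table::as.data.table(w$obs)
  wide <- dt[, .(v = mean(value)), by = .(station_id, param)]
  tmp <- wide[param == "temp"]$v[match(w$stations$station_id,
                                       wide[param == "temp"]$station_id)]
  rh <- wide[param == "rh"]$v[match(w$stations$station_id,
                                    wide[param == "rh"]$station_id)]
  expect_lt(cor(tmp, rh), 0)
})

test_that("a span shorter than the widest window is rejected", {
  expect_error(generate_world(world_config(n_strains = 5, n_markers = 10,
                                           n_stations = 5, span_years = 2,
                                           seed = 1)),
               "span shorter")
})

test_that("competition counts follow the logistic decay with binomial
           droplet noise", {
  # neutrality: frequency stays at p0
  cc1 <- generate_competition_counts(0.5, 1, c(2, 4, 6), droplets = 5000,
                                     replicates = 20, seed = 9)
  fr <- allele_frequencies(cc1)
  expect_equal(mean(fr$p), 0.5, tolerance = 0.01)

  # closed form: p0 = 0.5, w = 2.151 -> p6 ~ 0.01
  p6 <- plogis(qlogis(0.5) - 6 * log((0.99 / 0.01)^(1 / 6)))
  expect_equal(p6, 0.01, tolerance = 1e-12)
  cc2 <- generate_competition_counts(0.5, (0.99 / 0.01)^(1 / 6), 6,
                                     droplets = 1e5, replicates = 30,
                                     seed = 10)
  expect_equal(mean(allele_frequencies(cc2)$p), 0.01, tolerance = 0.05)

  # law of large numbers: big droplet counts converge to the trajectory
  w_rel <- 1.6
  cc3 <- generate_competition_counts(0.5, w_rel, c(2, 4, 6), droplets = 1e5,
                                     replicates = 5, seed = 11)
  fr3 <- allele_frequencies(cc3)
  p_det <- plogis(qlogis(0.5) - fr3$transfer * log(w_rel))
  expect_lt(max(abs(fr3$p - p_det)), 0.005)

  expect_error(generate_competition_counts(0.5, 1.5, droplets = 0),
               "droplets")
  expect_error(generate_competition_counts(0, 1.5), "p0")
  expect_error(generate_competition_counts(0.5, -1), "w_rel")
})

test_that("world round-trips through the plain-text writers", {
  w <- fixture_small_world(seed = 4, n_strains = 12, n_markers = 30,
                           n_stations = 8)
  dir <- tempfile("world_")
  write_world(w, dir)
  rec <- read_isolation_records(file.path(dir, "isolation.tsv"))
  expect_equal(rec$strain, w$records$strain)
  expect_equal(rec$date_precision, w$records$date_precision)
  G <- read_genotypes_tsv(file.path(dir, "genotypes.tsv"))
  expect_equal(unname(G), unname(w$genotypes), ignore_attr = TRUE)
  Gv <- read_genotypes_vcf(file.path(dir, "genotypes.vcf"))
  expect_equal(unname(Gv), unname(w$genotypes), ignore_attr = TRUE)
  expect_equal(rownames(Gv), rownames(w$genotypes))
  mk <- attr(Gv, "markers")
  expect_equal(mk$chrom, attr(w$genotypes, "markers")$chrom)
  tr <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(tr$causal_effect_degC, 0)
  unlink(dir, recursive = TRUE)
})
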