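# MAF filter, kinship, EMMA variance components, marker tests, QTL calling,
# peak splits, LD.

test_that("MAF filter retains markers at >= 5% minor allele frequency over
           non-missing strains", {
  n <- 152
  G <- cbind(m1 = c(rep(1, 7), rep(0, n - 7)),    # 4.6% -> removed
             m2 = c(rep(1, 8), rep(0, n - 8)),    # 5.26% -> retained
             m3 = rep(0, n),                      # monomorphic -> removed
             m4 = c(rep(1, 80), rep(0, n - 80)))
  rownames(G) <- sprintf("s%03d", 1:n)
  out <- maf_filter(G)
  expect_setequal(colnames(out), c("m2", "m4"))

  # missing genotypes excluded from the frequency
  G2 <- cbind(m = c(rep(1, 5), rep(0, 95), rep(NA, 52)))
  expect_equal(colnames(maf_filter(G2)), "m")  # 5/100 = 5%
  expect_error(maf_filter(cbind(z = rep(0, 10))), "all markers removed")
})

test_that("kinship equals the brute-force centered cross-product and is a
           symmetric PSD matrix with duplicate strains maximal", {
  set.seed(15)
  G <- matrix(rbinom(5 * 20, 1, runif(20, 0.2, 0.8)), 5, 20, byrow = TRUE)
  dimnames(G) <- list(paste0("s", 1:5), paste0("m", 1:20))
  K <- kinship(G)
  # independent direct computation of the VanRaden form
  p <- colMeans(G)
  poly <- p > 0 & p < 1
  W <- sweep(2 * G[, poly] - 1, 2, 2 * p[poly] - 1)
  K_oracle <- W %*% t(W) / (2 * sum(p[poly] * (1 - p[poly])))
  expect_equal(unname(K), unname(K_oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-8)

  # identical strains: off-diagonal equals the diagonal entry
  G2 <- rbind(G, dup = G[1, ])
  K2 <- kinship(G2)
  expect_equal(K2["s1", "dup"], K2["s1", "s1"])

  # missing genotypes are mean-imputed, zero-variance markers skipped
  G3 <- G; G3[2, 1] <- NA
  expect_silent(kinship(G3))
  expect_equal(attr(kinship(cbind(G, flat = 1)), "n_markers"),
               sum(poly))
})

test_that("Bonferroni thresholds match the closed form", {
  expect_equal(bonferroni_threshold(1), -log10(0.05), tolerance = 1e-12)
  expect_equal(bonferroni_threshold(100), 3.301, tolerance = 1e-3)
  expect_equal(bonferroni_threshold(10000), 5.301, tolerance = 1e-3)
})

test_that("the null model recovers variance components; flat likelihood
           (K = I) reads as no genetic variance", {
  set.seed(16)
  n <- 60
  y <- rnorm(n)
  vc <- fit_null_model(y, diag(n))
  expect_lt(vc$heritability, 0.01)

  # returned optimum dominates the whole grid
  expect_true(all(vc$rll >= vc$grid_rll - 1e-8))

  expect_error(fit_null_model(rep(1, n), diag(n)), "constant")
  expect_error(fit_null_model(y, -diag(n)), "positive semidefinite")
})

test_that("heritability is recovered on simulated polygenic traits", {
  G <- generate_genotypes(world_config(n_strains = 150, n_markers = 500,
                                       seed = 17))
  K <- kinship(G)
  eK <- eigen(K, symmetric = TRUE)
  L <- eK$vectors %*% diag(sqrt(pmax(eK$values, 0)))
  set.seed(18)
  h2 <- replicate(60, {
    u <- sqrt(2) * as.numeric(L %*% rnorm(150))
    fit_null_model(u + rnorm(150), K)$heritability
  })
  expect_equal(median(h2), 2 / 3, tolerance = 0.1 / (2 / 3))
})

test_that("with K = I and no genetic variance the marker test reduces
           exactly to the OLS t-test", {
  set.seed(19)
  n <- 20
  y <- rnorm(n)
  x <- rbinom(n, 1, 0.5)
  vc <- list(sigma_g2 = 0, sigma_e2 = 1, d = rep(1, n), U = diag(n))
  mt <- marker_test(y, x, diag(n), vc)
  ols <- summary(lm(y ~ x))$coefficients[2, ]
  expect_equal(mt$beta, unname(ols[1]), tolerance = 1e-10)
  expect_equal(mt$se, unname(ols[2]), tolerance = 1e-10)
  expect_equal(mt$p, unname(ols[4]), tolerance = 1e-10)

  # a constant marker is flagged, not an error
  mt0 <- marker_test(y, rep(1, n), diag(n), vc)
  expect_true(mt0$constant)
  expect_equal(mt0$p, 1)

  # the vectorised scan agrees with the per-marker test
  G <- cbind(a = x, b = rbinom(n, 1, 0.4))
  rownames(G) <- paste0("s", 1:n)
  sc <- nichemap:::.emma_scan(y, G, vc)
  expect_equal(sc$p[1], mt$p, tolerance = 1e-10)
  mtb <- marker_test(y, G[, "b"], diag(n), vc)
  expect_equal(sc$p[2], mtb$p, tolerance = 1e-10)
})

test_that("QTL calling groups significant markers by merge radius with a
           leftmost-tie peak, and is order invariant", {
  mk <- function(chrom, pos, lp)
    data.frame(marker = sprintf("%s_%d", chrom, pos), chrom = chrom,
               pos = pos, beta = 0, se = 1, p = 10^-lp, neglog10p = lp)
  # single significant marker: radius-padded point interval
  m <- do.call(rbind, lapply(1:100, function(i)
    mk("I", i * 1000, if (i == 50) 6 else 1)))
  q <- call_qtl(m, merge_radius = 5, threshold = 4)
  expect_equal(nrow(q), 1)
  expect_equal(q$peak_pos, 50000)
  expect_equal(q$start, 45000)
  expect_equal(q$end, 55000)
  expect_true(q$start <= q$peak_pos && q$peak_pos <= q$end)

  # two clusters far apart on one chromosome are two QTL
  m2 <- do.call(rbind, lapply(1:200, function(i)
    mk("II", i * 1e5, if (i %in% c(10, 11, 150)) 6 else 1)))
  q2 <- call_qtl(m2, merge_radius = 10, threshold = 4)
  expect_equal(nrow(q2), 2)

  # tie on -log10(p): leftmost peak wins
  m3 <- do.call(rbind, lapply(1:20, function(i)
    mk("III", i * 1000, if (i %in% c(8, 12)) 6 else 1)))
  q3 <- call_qtl(m3, merge_radius = 10, threshold = 4)
  expect_equal(q3$peak_pos, 8000)

  # nothing significant: empty, not an error
  expect_equal(nrow(call_qtl(m[m$neglog10p < 4, ], threshold = 4)), 0)

  # shuffling marker order does not change the calls
  set.seed(20)
  q2b <- call_qtl(m2[sample(nrow(m2)), ], merge_radius = 10, threshold = 4)
  expect_equal(q2b, q2)
  # idempotence under re-calling
  expect_equal(call_qtl(m2, merge_radius = 10, threshold = 4), q2)
})

test_that("peak-genotype splits partition the strains and are null for
           identical groups", {
  y <- setNames(c(rnorm(10, 5), rnorm(10, 5)), paste0("s", 1:20))
  x <- setNames(rep(c(0, 1), each = 10), paste0("s", 1:20))
  s <- split_by_peak_genotype(y, x)
  expect_equal(sum(s$n), 20)
  expect_setequal(s$genotype, c("REF", "ALT"))

  y2 <- setNames(rep(c(1, 2), 10), paste0("s", 1:20))
  x2 <- setNames(rep(0:1, 10), paste0("s", 1:20))
  s2 <- split_by_peak_genotype(rep(3, 20) * 0 + y2 * 0 + 5, x2)
  expect_equal(s2$mean[1], s2$mean[2])

  # empty group flagged with n = 0
  s3 <- split_by_peak_genotype(y, setNames(rep(0, 20), names(y)))
  expect_equal(s3$n[s3$genotype == "ALT"], 0)
})

test_that("LD r2 equals the haplotype-frequency D^2 form for 0/1 markers", {
  set.seed(22)
  x <- rbinom(40, 1, 0.5)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 1 - x), 1)

  y <- rbinom(40, 1, 0.5)
  p <- mean(x); q <- mean(y)
  D <- mean(x * y) - p * q
  expect_equal(ld_r2(x, y), D^2 / (p * (1 - p) * q * (1 - q)))
  expect_true(is.na(ld_r2(x, rep(1, 40))))
})

test_that("gwas_scan supports separate kinship and test marker sets and
           reports a classed result", {
  cfg <- world_config(n_strains = 80, n_markers = 300, seed = 23)
  G_rad <- generate_genotypes(cfg)
  cfg2 <- world_config(n_strains = 80, n_markers = 500, seed = 23)
  G_wgs <- generate_genotypes(cfg2)
  set.seed(24)
  y <- setNames(rnorm(80), rownames(G_rad))
  sc <- gwas_scan(y, G_rad, kinship_G = G_wgs)
  expect_s3_class(sc, "gwas_scan")
  expect_equal(nrow(sc$mapping), ncol(maf_filter(G_rad)))
  expect_true(all(sc$mapping$p > 0 & sc$mapping$p <= 1))
  expect_true(all(is.finite(sc$mapping$neglog10p)))
  expect_output(print(sc), "Kinship-corrected")
})
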