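# EMMA: exact restricted-likelihood variance components by spectral
# decomposition of the kinship matrix, and the P3D single-marker scan.

# Restricted log-likelihood profile in delta = sigma_e^2 / sigma_g^2,
# given eigenvalues xi and rotated residuals eta of S K S.
.emma_rll <- function(delta, xi, eta2) {
  m <- length(xi)
  denom <- xi + delta
  0.5 * (m * (log(m / (2 * pi)) - 1 - log(sum(eta2 / denom))) -
           sum(log(denom)))
}

.emma_drll <- function(delta, xi, eta2) {
  m <- length(xi)
  denom <- xi + delta
  0.5 * (m * sum(eta2 / denom^2) / sum(eta2 / denom) - sum(1 / denom))
}

#' Fit the null mixed model (EMMA REML)
#'
#' Fits y = X b + u + e with u ~ N(0, sigma_g^2 K), e ~ N(0, sigma_e^2 I)
#' by restricted maximum likelihood. The restricted likelihood is profiled
#' over delta = sigma_e^2 / sigma_g^2 on the spectrum of S K S (S the
#' projection orthogonal to X): a grid over log10(delta) in \[-5, 5\] (100
#' points) followed by derivative-based root refinement in every bracketing
#' interval. When the profile is flat (K proportional to I makes the two
#' components unidentifiable) the largest near-optimal delta is returned,
#' i.e. the no-genetic-variance reading.
#'
#' @param y trait vector (complete cases only; strains with missing trait
#'   must be dropped by the caller or via `na.omit`).
#' @param K kinship matrix conformable with `y`.
#' @param X fixed-effect design matrix (default intercept only).
#' @param grid_points number of grid points over log10(delta).
#' @return list of class `emma_vc`: `sigma_g2`, `sigma_e2`, `delta`,
#'   `heritability`, `rll` (restricted log-likelihood at the optimum), plus
#'   the eigen-rotation (`U`, `d`) of K reused by the marker scan.
#' @export
fit_null_model <- function(y, K, X = NULL, grid_points = 100L) {
  stopifnot(is.numeric(y), nrow(K) == length(y))
  if (anyNA(y)) stop("y contains missing values; drop them first")
  if (var(y) == 0) stop("constant trait")
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  q <- ncol(X)
  eK <- eigen(K, symmetric = TRUE)
  if (min(eK$values) < -1e-8 * max(abs(eK$values)))
    stop("K is not positive semidefinite within tolerance")
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  eS <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- eS$values[seq_len(n - q)]
  xi[xi < 0] <- 0
  eta <- crossprod(eS$vectors[, seq_len(n - q), drop = FALSE], y)
  eta2 <- as.numeric(eta)^2
  lgrid <- seq(-5, 5, length.out = grid_points)
  dgrid <- 10^lgrid
  rll <- vapply(dgrid, .emma_rll, numeric(1), xi = xi, eta2 = eta2)
  drv <- vapply(dgrid, .emma_drll, numeric(1), xi = xi, eta2 = eta2)
  cand_delta <- dgrid
  cand_rll <- rll
  # refine every sign change of the derivative
  brackets <- which(drv[-length(drv)] > 0 & drv[-1] < 0)
  for (b in brackets) {
    r <- tryCatch(uniroot(.emma_drll, c(dgrid[b], dgrid[b + 1]),
                          xi = xi, eta2 = eta2, tol = 1e-10),
                  error = function(e) NULL)
    if (!is.null(r)) {
      cand_delta <- c(cand_delta, r$root)
      cand_rll <- c(cand_rll, .emma_rll(r$root, xi, eta2))
    }
  }
  best <- max(cand_rll)
  near <- which(cand_rll >= best - 1e-6)
  pick <- near[which.max(cand_delta[near])]  # flat profile -> largest delta
  delta <- cand_delta[pick]
  sigma_g2 <- sum(eta2 / (xi + delta)) / (n - q)
  sigma_e2 <- delta * sigma_g2
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
                 heritability = sigma_g2 / (sigma_g2 + sigma_e2),
                 rll = cand_rll[pick], U = eK$vectors, d = pmax(eK$values, 0),
                 grid_delta = dgrid, grid_rll = rll),
            class = "emma_vc")
}

#' Single-marker mixed-model test
#'
#' Generalized least squares on data decorrelated by the kinship
#' eigen-rotation: rows are rotated by U' and weighted by
#' (sigma_g^2 d_i + sigma_e^2)^(-1/2), then the marker coefficient gets an
#' ordinary t-test with n - 2 degrees of freedom. Variance components are
#' fixed from the null fit (P3D); `exact = TRUE` re-estimates them per
#' marker. With K = I and sigma_g^2 = 0 this reduces exactly to the OLS
#' t-test.
#'
#' @param y trait vector.
#' @param x marker genotype vector (0/1; `NA` mean-imputed).
#' @param K kinship matrix.
#' @param vc null-model fit from [fit_null_model()].
#' @param exact refit variance components with the marker in the model.
#' @return list `beta`, `se`, `p`, `df`, `constant` (flag for degenerate
#'   markers, which get p = 1).
#' @export
marker_test <- function(y, x, K, vc, exact = FALSE) {
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  if (var(x) == 0)
    return(list(beta = NA_real_, se = NA_real_, p = 1, df = NA_integer_,
                constant = TRUE))
  n <- length(y)
  if (exact) vc <- fit_null_model(y, K, X = cbind(1, x))
  w <- 1 / sqrt(vc$sigma_g2 * vc$d + vc$sigma_e2)
  yt <- w * crossprod(vc$U, y)
  Xt <- w * crossprod(vc$U, cbind(1, x))
  fit <- stats::lm.fit(Xt, yt)
  df <- n - 2L
  s2 <- sum(fit$residuals^2) / df
  XtXi <- chol2inv(chol(crossprod(Xt)))
  se <- sqrt(s2 * XtXi[2, 2])
  beta <- unname(fit$coefficients[2])
  tval <- beta / se
  list(beta = beta, se = se, p = 2 * pt(-abs(tval), df), df = df,
       constant = FALSE)
}

# Vectorised P3D scan over all markers (same math as marker_test, closed
# forms for the two-regressor GLS). Returns data.frame beta/se/p.
.emma_scan <- function(y, G, vc) {
  n <- length(y)
  w <- 1 / sqrt(vc$sigma_g2 * vc$d + vc$sigma_e2)
  Ut <- t(vc$U)
  yt <- as.numeric(w * (Ut %*% y))
  ones <- as.numeric(w * (Ut %*% rep(1, n)))
  Gi <- G
  if (anyNA(Gi)) {
    mu <- colMeans(Gi, na.rm = TRUE)
    idx <- which(is.na(Gi), arr.ind = TRUE)
    Gi[idx] <- mu[idx[, 2]]
  }
  Xt <- w * (Ut %*% Gi)
  a <- sum(ones^2)
  b <- as.numeric(crossprod(ones, Xt))
  cc <- colSums(Xt^2)
  u <- sum(ones * yt)
  v <- as.numeric(crossprod(Xt, yt))
  syy <- sum(yt^2)
  det <- a * cc - b^2
  const <- apply(Gi, 2, var) == 0
  det[const] <- NA
  beta0 <- (cc * u - b * v) / det
  beta1 <- (a * v - b * u) / det
  rss <- syy - beta0 * u - beta1 * v
  df <- n - 2L
  s2 <- rss / df
  se <- sqrt(s2 * a / det)
  tval <- beta1 / se
  p <- 2 * pt(-abs(tval), df)
  p[const] <- 1
  data.frame(marker = colnames(G), beta = beta1, se = se, p = p,
             constant = const, stringsAsFactors = FALSE)
}
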