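# Relative fitness from two-strain competition allele-count trajectories.

#' Allele frequencies from a count trajectory
#'
#' p_t = count_A / (count_A + count_B) per time point; time points with a
#' zero total are dropped. Boundary frequencies (0 or 1) are flagged for
#' the log-odds fit.
#'
#' @param counts data.frame with `transfer`, `count_A`, `count_B` (and any
#'   grouping columns, which are carried through).
#' @return `counts` with added `p` and `boundary` columns, zero-total rows
#'   removed.
#' @export
allele_frequencies <- function(counts) {
  tot <- counts$count_A + counts$count_B
  keep <- tot > 0
  if (!all(keep)) counts <- counts[keep, , drop = FALSE]
  tot <- tot[keep]
  counts$p <- counts$count_A / tot
  counts$boundary <- counts$p == 0 | counts$p == 1
  counts
}

#' Relative fitness from one frequency trajectory
#'
#' Fits the per-transfer logistic decay
#' `logit(p_t) = logit(p0) - t * log(w_rel)` by weighted least squares over
#' transfer index t. The intercept is fixed at `logit(p0)` by default (the
#' assay seeds equal numbers of both strains, so p0 = 0.5 is known by
#' design); `fix_intercept = FALSE` frees it. When allele counts are
#' supplied, boundary frequencies receive the Haldane continuity correction
#' (+0.5 to each allele count) and points are weighted by the delta-method
#' information of the logit, n * p * (1 - p); frequency-only input is fit
#' unweighted and boundary points are an error.
#'
#' @param transfer transfer indices.
#' @param p observed A-allele frequencies (or `NULL` to derive from counts).
#' @param count_A,count_B optional allele counts.
#' @param p0 known initial frequency.
#' @param fix_intercept fix the intercept at `logit(p0)`.
#' @return list: `w_rel` (relative fitness of the B strain per transfer,
#'   1 = neutral), `log_w` and its `se` from the fit.
#' @export
estimate_relative_fitness <- function(transfer, p = NULL, count_A = NULL,
                                      count_B = NULL, p0 = 0.5,
                                      fix_intercept = TRUE) {
  stopifnot(p0 > 0, p0 < 1)
  if (is.null(p)) {
    stopifnot(!is.null(count_A), !is.null(count_B))
    tot <- count_A + count_B
    keep <- tot > 0
    transfer <- transfer[keep]
    count_A <- count_A[keep]; count_B <- count_B[keep]
    bound <- count_A == 0 | count_B == 0
    a <- count_A + 0.5 * bound
    b <- count_B + 0.5 * bound
    p <- a / (a + b)
    wts <- (a + b) * p * (1 - p)
  } else {
    if (any(p <= 0 | p >= 1))
      stop("boundary frequencies need counts for the continuity correction")
    wts <- rep(1, length(p))
  }
  if (length(p) < 1) stop("no usable time points")
  z <- qlogis(p)
  z0 <- qlogis(p0)
  if (fix_intercept) {
    num <- sum(wts * transfer * (z0 - z))
    den <- sum(wts * transfer^2)
    log_w <- num / den
    resid <- (z - (z0 - transfer * log_w))
    dfree <- length(z) - 1L
    se <- if (dfree > 0)
      sqrt(sum(wts * resid^2) / dfree / den) else NA_real_
  } else {
    if (length(z) < 2) stop("free-intercept fit needs >= 2 time points")
    fit <- stats::lm(z ~ transfer, weights = wts)
    log_w <- -unname(coef(fit)[2])
    se <- summary(fit)$coefficients[2, 2]
  }
  list(w_rel = exp(log_w), log_w = log_w, se = se)
}

#' Per-timepoint replicate summaries of allele frequency
#'
#' Mean and standard deviation of p_t across replicates, per temperature
#' and transfer. With a single replicate the SD is reported missing.
#'
#' @param counts count table (`temperature`, `replicate`, `transfer`,
#'   `count_A`, `count_B`).
#' @return data.frame: temperature, transfer, n, mean_p, sd_p.
#' @export
summarize_replicates <- function(counts) {
  fr <- allele_frequencies(counts)
  dt <- data.table::as.data.table(fr)
  out <- dt[, .(n = .N, mean_p = mean(p),
                sd_p = if (.N > 1) sd(p) else NA_real_),
            by = .(temperature, transfer)]
  data.table::setorder(out, temperature, transfer)
  as.data.frame(out)
}

#' Fit relative fitness from a competition count table
#'
#' Per temperature, fits each replicate's trajectory with
#' [estimate_relative_fitness()] and pools replicates by the mean of the
#' per-replicate log fitness, with the standard error of that mean.
#'
#' @param counts count table (`temperature`, `replicate`, `transfer`,
#'   `count_A`, `count_B`).
#' @param p0 initial A-allele frequency (0.5 by the equal-seeding design).
#' @param fix_intercept fix the intercept at `logit(p0)`.
#' @return object of class `competition_fit`: `estimates` (temperature,
#'   n_replicates, w_rel, log_w, se_log_w, se_w), `replicates`
#'   (per-replicate fits), `trajectory` (per-timepoint mean +/- SD).
#' @export
competition_fit <- function(counts, p0 = 0.5, fix_intercept = TRUE) {
  stopifnot(all(c("replicate", "transfer", "count_A", "count_B") %in%
                  names(counts)))
  if (!"temperature" %in% names(counts)) counts$temperature <- NA
  reps <- do.call(rbind, lapply(
    split(counts, list(counts$temperature, counts$replicate), drop = TRUE),
    function(d) {
      est <- estimate_relative_fitness(d$transfer, count_A = d$count_A,
                                       count_B = d$count_B, p0 = p0,
                                       fix_intercept = fix_intercept)
      data.frame(temperature = d$temperature[1], replicate = d$replicate[1],
                 w_rel = est$w_rel, log_w = est$log_w)
    }))
  rownames(reps) <- NULL
  dt <- data.table::as.data.table(reps)
  est <- as.data.frame(dt[, {
    lw <- mean(log_w)
    se <- if (.N > 1) sd(log_w) / sqrt(.N) else NA_real_
    .(n_replicates = .N, w_rel = exp(lw), log_w = lw, se_log_w = se,
      se_w = exp(lw) * se)
  }, by = temperature])
  structure(list(estimates = est, replicates = reps,
                 trajectory = summarize_replicates(counts), p0 = p0,
                 fix_intercept = fix_intercept),
            class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("Two-strain competition fitness fit\n")
  cat(sprintf("  model: logit(p_t) = logit(%g) - t * log(w_rel)%s\n", x$p0,
              if (x$fix_intercept) " (intercept fixed)" else ""))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' @export
coef.competition_fit <- function(object, ...) {
  setNames(object$estimates$w_rel, object$estimates$temperature)
}

#' @export
summary.competition_fit <- function(object, ...) {
  print(object)
  cat("\nTrajectory (mean +/- SD of A-allele frequency):\n")
  print(object$trajectory, row.names = FALSE)
  invisible(object)
}

#' Trajectory plot of a competition fit
#' @param x a `competition_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.competition_fit <- function(x, ...) {
  tr <- x$trajectory
  temps <- unique(tr$temperature)
  cols <- setNames(seq_along(temps) + 1, temps)
  plot(range(c(0, tr$transfer)), c(0, max(x$p0, tr$mean_p, na.rm = TRUE)),
       type = "n", xlab = "culture transfer", ylab = "A-allele frequency",
       ...)
  for (tm in temps) {
    d <- tr[tr$temperature == tm, ]
    points(c(0, d$transfer), c(x$p0, d$mean_p), type = "b", pch = 19,
           col = cols[[as.character(tm)]])
    ok <- !is.na(d$sd_p)
    segments(d$transfer[ok], d$mean_p[ok] - d$sd_p[ok],
             d$transfer[ok], d$mean_p[ok] + d$sd_p[ok],
             col = cols[[as.character(tm)]])
  }
  legend("topright", legend = temps, col = cols, pch = 19, bty = "n")
  invisible(x)
}
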