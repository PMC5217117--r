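# Genome-wide association: MAF filter, significance threshold, the scan
# object, QTL calling, peak-genotype splits, LD.

#' Filter markers by minor allele frequency
#'
#' Retains markers whose minor-allele frequency, computed over non-missing
#' strains, is at least `min_maf` (default 5%). Monomorphic markers are
#' removed.
#'
#' @param G strains x markers 0/1 matrix (marker metadata attribute is
#'   subset along).
#' @param min_maf minimum MAF.
#' @return filtered matrix.
#' @export
maf_filter <- function(G, min_maf = 0.05) {
  p <- colMeans(G, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= min_maf & p > 0 & p < 1
  if (!any(keep)) stop("all markers removed by MAF filter")
  out <- G[, keep, drop = FALSE]
  mk <- attr(G, "markers")
  if (!is.null(mk)) attr(out, "markers") <- mk[keep, , drop = FALSE]
  out
}

#' Bonferroni significance threshold on the -log10 scale
#' @param n_markers number of tested markers.
#' @param alpha family-wise error rate.
#' @return -log10(alpha / n_markers).
#' @export
bonferroni_threshold <- function(n_markers, alpha = 0.05) {
  stopifnot(n_markers >= 1, alpha > 0, alpha < 1)
  -log10(alpha / n_markers)
}

#' Kinship-corrected association scan
#'
#' The package's central fitting function: fits the EMMA null model for a
#' trait, runs the P3D single-marker scan over all markers, applies the
#' Bonferroni threshold and calls QTL. Strains with a missing trait value
#' are dropped listwise; trait values are used untransformed and outliers
#' are kept.
#'
#' @param y named trait vector (names = strains) or a trait table column.
#' @param G strains x markers 0/1 genotype matrix with optional `"markers"`
#'   metadata (chromosome, position).
#' @param K kinship matrix; computed from `kinship_G` (or `G`) when `NULL`.
#' @param kinship_G optional dense marker set for the kinship (the
#'   whole-genome set, as opposed to the sparse tested set).
#' @param min_maf MAF filter applied to tested markers.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param merge_radius markers: significant markers closer than this (in
#'   marker index within a chromosome) join one QTL, and intervals are
#'   padded by it.
#' @param exact re-estimate variance components per marker instead of P3D.
#' @return object of class `gwas_scan`: `mapping` (marker, chrom, pos,
#'   beta, se, p, neglog10p, significant), `vc`, `threshold`, `qtl`, `n`.
#' @export
gwas_scan <- function(y, G, K = NULL, kinship_G = NULL, min_maf = 0.05,
                      alpha = 0.05, merge_radius = 50L, exact = FALSE) {
  if (is.null(names(y)) && length(y) == nrow(G)) names(y) <- rownames(G)
  keep <- names(y)[!is.na(y)]
  keep <- intersect(keep, rownames(G))
  if (length(keep) < 3) stop("fewer than 3 strains with trait and genotype")
  y <- y[keep]
  mk_attr <- attr(G, "markers")
  G <- G[keep, , drop = FALSE]
  attr(G, "markers") <- mk_attr
  if (is.null(K)) {
    KG <- if (is.null(kinship_G)) G else kinship_G[keep, , drop = FALSE]
    K <- kinship(KG)
  } else {
    K <- K[keep, keep]
  }
  G <- maf_filter(G, min_maf)
  vc <- fit_null_model(y, K)
  if (exact) {
    res <- do.call(rbind, lapply(seq_len(ncol(G)), function(j) {
      r <- marker_test(y, G[, j], K, vc, exact = TRUE)
      data.frame(marker = colnames(G)[j], beta = r$beta, se = r$se,
                 p = r$p, constant = r$constant)
    }))
  } else {
    res <- .emma_scan(y, G, vc)
  }
  mk <- attr(G, "markers")
  if (is.null(mk))
    mk <- data.frame(marker = colnames(G), chrom = "I",
                     pos = seq_len(ncol(G)))
  mapping <- data.frame(marker = res$marker,
                        chrom = mk$chrom[match(res$marker, mk$marker)],
                        pos = mk$pos[match(res$marker, mk$marker)],
                        beta = res$beta, se = res$se, p = res$p,
                        neglog10p = -log10(pmax(res$p, .Machine$double.xmin)),
                        stringsAsFactors = FALSE)
  thr <- bonferroni_threshold(nrow(mapping), alpha)
  mapping$significant <- mapping$neglog10p > thr
  qtl <- call_qtl(mapping, merge_radius = merge_radius, threshold = thr)
  structure(list(mapping = mapping, vc = vc, threshold = thr, qtl = qtl,
                 n = length(y), y = y, G = G, alpha = alpha),
            class = "gwas_scan")
}

#' Group significant markers into QTL
#'
#' Significant markers on the same chromosome whose within-chromosome index
#' gap is at most `merge_radius` form one QTL. The peak is the marker with
#' the largest -log10(p) (leftmost position on ties); the interval spans
#' the leftmost to rightmost significant marker of the group, extended by
#' `merge_radius` markers on each side (clamped to the chromosome).
#'
#' @param mapping mapping data.frame (as in [gwas_scan()]), ordered or not.
#' @param merge_radius marker-index merge radius.
#' @param threshold -log10(p) significance threshold (recomputed by
#'   Bonferroni when `NULL`).
#' @param alpha used when `threshold` is `NULL`.
#' @return data.frame of QTL: chrom, start, peak_marker, peak_pos, end,
#'   peak_neglog10p, n_markers.
#' @export
call_qtl <- function(mapping, merge_radius = 50L, threshold = NULL,
                     alpha = 0.05) {
  if (is.null(threshold)) threshold <- bonferroni_threshold(nrow(mapping), alpha)
  mapping <- mapping[order(mapping$chrom, mapping$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(mapping$chrom)) {
    m <- mapping[mapping$chrom == ch, , drop = FALSE]
    sig <- which(m$neglog10p > threshold)
    if (!length(sig)) next
    grp <- cumsum(c(1, diff(sig) > merge_radius))
    for (g in unique(grp)) {
      idx <- sig[grp == g]
      pk <- idx[order(-m$neglog10p[idx], m$pos[idx])][1]
      lo <- max(1L, min(idx) - merge_radius)
      hi <- min(nrow(m), max(idx) + merge_radius)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = m$pos[lo], peak_marker = m$marker[pk],
        peak_pos = m$pos[pk], end = m$pos[hi],
        peak_neglog10p = m$neglog10p[pk], n_markers = length(idx),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      peak_marker = character(), peak_pos = numeric(),
                      end = numeric(), peak_neglog10p = numeric(),
                      n_markers = integer()))
  do.call(rbind, out)
}

#' Trait summaries split by genotype at a peak marker
#'
#' REF (0, the reference-strain genotype) vs ALT (1) group sizes, means,
#' medians and quartiles of the trait at a QTL peak.
#'
#' @param y named trait vector.
#' @param x named 0/1 genotype vector at the peak marker.
#' @return data.frame with one row per genotype group; empty groups are
#'   flagged via `n = 0`.
#' @export
split_by_peak_genotype <- function(y, x) {
  if (!is.null(names(y)) && !is.null(names(x))) {
    common <- intersect(names(y), names(x))
    y <- y[common]; x <- x[common]
  }
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  do.call(rbind, lapply(c(REF = 0, ALT = 1), function(g) {
    v <- y[x == g]
    if (!length(v))
      return(data.frame(genotype = names(which(c(REF = 0, ALT = 1) == g)),
                        n = 0L, mean = NA_real_, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_))
    data.frame(genotype = if (g == 0) "REF" else "ALT", n = length(v),
               mean = mean(v), median = median(v),
               q25 = unname(quantile(v, 0.25)),
               q75 = unname(quantile(v, 0.75)))
  }))
}

#' Linkage disequilibrium r-squared between two markers
#'
#' Squared Pearson correlation of the 0/1 genotype vectors over shared
#' strains (for haploid coding this equals D^2 / (p q (1-p)(1-q))).
#'
#' @param x_i,x_j 0/1 genotype vectors.
#' @return r^2, or `NA` if either marker is constant.
#' @export
ld_r2 <- function(x_i, x_j) {
  ok <- !is.na(x_i) & !is.na(x_j)
  x_i <- x_i[ok]; x_j <- x_j[ok]
  if (var(x_i) == 0 || var(x_j) == 0) return(NA_real_)
  cor(x_i, x_j)^2
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat("Kinship-corrected association scan (EMMA)\n")
  cat(sprintf("  strains: %d, markers tested: %d\n", x$n, nrow(x$mapping)))
  cat(sprintf("  variance components: sigma_g2 = %.4g, sigma_e2 = %.4g (h2 = %.3f)\n",
              x$vc$sigma_g2, x$vc$sigma_e2, x$vc$heritability))
  cat(sprintf("  Bonferroni threshold: -log10(p) > %.3f (alpha = %g)\n",
              x$threshold, x$alpha))
  cat(sprintf("  significant markers: %d; QTL called: %d\n",
              sum(x$mapping$significant), nrow(x$qtl)))
  invisible(x)
}

#' @export
summary.gwas_scan <- function(object, ...) {
  print(object)
  if (nrow(object$qtl)) {
    cat("\nQTL:\n")
    print(object$qtl, row.names = FALSE)
    cat("\nPeak-genotype splits:\n")
    for (i in seq_len(nrow(object$qtl))) {
      pk <- object$qtl$peak_marker[i]
      cat(sprintf("  %s (%s:%d-%d)\n", pk, object$qtl$chrom[i],
                  object$qtl$start[i], object$qtl$end[i]))
      print(split_by_peak_genotype(object$y, object$G[, pk]),
            row.names = FALSE)
    }
  }
  invisible(object)
}

#' Manhattan plot of a scan
#' @param x a `gwas_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gwas_scan <- function(x, ...) {
  m <- x$mapping[order(x$mapping$chrom, x$mapping$pos), ]
  chroms <- unique(m$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(m$pos[m$chrom == ch]), numeric(1))))
  xpos <- m$pos + offs[match(m$chrom, chroms)]
  plot(xpos, m$neglog10p, pch = 20, cex = 0.5,
       col = ifelse(m$significant, "red",
                    c("black", "grey40")[1 + match(m$chrom, chroms) %% 2]),
       xlab = "genomic position", ylab = expression(-log[10](p)), xaxt = "n",
       ...)
  abline(h = x$threshold, lty = 2, col = "grey")
  axis(1, at = offs[-length(offs)] + diff(offs) / 2, labels = chroms)
  invisible(x)
}
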