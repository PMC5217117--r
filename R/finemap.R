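# Fine mapping: rank correlation of trait values with moderate/severe
# variants inside a QTL interval, and gene-level candidate ranking.

#' Select annotated variants inside a QTL interval
#'
#' Intervals are 1-based and inclusive on both ends. Only variants of
#' moderate or severe predicted functional impact are admitted.
#'
#' @param annotations data.frame: `marker` (or `variant`), `chrom`, `pos`,
#'   `gene`, `impact`.
#' @param qtl a one-row QTL data.frame (`chrom`, `start`, `end`) or a list
#'   with those fields.
#' @return the selected annotation subset.
#' @export
select_interval_variants <- function(annotations, qtl) {
  if (!"marker" %in% names(annotations) && "variant" %in% names(annotations))
    names(annotations)[names(annotations) == "variant"] <- "marker"
  keep <- annotations$chrom == qtl$chrom &
    annotations$pos >= qtl$start & annotations$pos <= qtl$end &
    annotations$impact %in% c("moderate", "severe")
  annotations[keep, , drop = FALSE]
}

#' Spearman fine mapping of a QTL interval
#'
#' Rank-correlates the trait with each selected variant's genotypes and
#' aggregates to genes by the best absolute correlation. Variants with a
#' constant genotype over the analyzed strains are skipped.
#'
#' @param y named trait vector.
#' @param G strains x markers 0/1 genotype matrix holding the variants.
#' @param variants annotation subset from [select_interval_variants()].
#' @return list of class `candidate_ranking`: `variants` (marker, gene,
#'   impact, rho, p, ordered by |rho| descending) and `genes` (gene,
#'   best_abs_rho, n_variants, ordered descending).
#' @export
spearman_fine_map <- function(y, G, variants) {
  if (is.null(names(y))) stop("y must be named by strain")
  keep <- names(y)[!is.na(y)]
  keep <- intersect(keep, rownames(G))
  if (length(keep) < 3) stop("fewer than 3 strains with trait and genotype")
  y <- y[keep]
  vars <- variants[variants$marker %in% colnames(G), , drop = FALSE]
  res <- lapply(seq_len(nrow(vars)), function(i) {
    x <- G[keep, vars$marker[i]]
    ok <- !is.na(x)
    if (sum(ok) < 3 || var(x[ok]) == 0) return(NULL)
    ct <- suppressWarnings(cor.test(y[ok], x[ok], method = "spearman"))
    data.frame(marker = vars$marker[i], gene = vars$gene[i],
               impact = vars$impact[i], rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  vt <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(vt))
    vt <- data.frame(marker = character(), gene = character(),
                     impact = character(), rho = numeric(), p = numeric())
  vt <- vt[order(-abs(vt$rho), vt$marker), , drop = FALSE]
  genes <- if (nrow(vt)) {
    dt <- data.table::as.data.table(vt)
    as.data.frame(dt[, .(best_abs_rho = max(abs(rho)), n_variants = .N),
                     by = gene][order(-best_abs_rho, gene)])
  } else {
    data.frame(gene = character(), best_abs_rho = numeric(),
               n_variants = integer())
  }
  structure(list(variants = vt, genes = genes), class = "candidate_ranking")
}

#' Shortlist candidate genes from a ranking
#'
#' Keeps genes whose best absolute rank correlation passes a threshold:
#' either an explicit `rho_cutoff`, or the top `top_fraction` of interval
#' genes (default 5%, at least one gene when any exist).
#'
#' @param ranking a `candidate_ranking`.
#' @param rho_cutoff absolute-rho cutoff (wins over `top_fraction`).
#' @param top_fraction fraction of interval genes to keep.
#' @return character vector of gene ids (best first).
#' @export
candidate_genes <- function(ranking, rho_cutoff = NULL, top_fraction = 0.05) {
  g <- ranking$genes
  if (!nrow(g)) return(character())
  if (!is.null(rho_cutoff)) return(g$gene[g$best_abs_rho > rho_cutoff])
  n <- max(1L, floor(nrow(g) * top_fraction))
  g$gene[seq_len(n)]
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat(sprintf("Fine mapping: %d testable variants in %d genes\n",
              nrow(x$variants), nrow(x$genes)))
  if (nrow(x$genes)) {
    cat("Top genes by best |rho|:\n")
    print(head(x$genes, 10), row.names = FALSE)
  }
  invisible(x)
}
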