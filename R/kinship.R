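# Realized-relationship (kinship) matrix from dense genotypes.

#' VanRaden realized-relationship matrix
#'
#' Computes the genomic kinship K = W W' / (2 * sum p (1 - p)) where the
#' 0/1 haploid genotypes are recoded to -1/1 and centered by twice the
#' alternative-allele frequency (W = M + 1 - 2p), the standard
#' realized-relationship construction for inbred panels. Missing genotypes
#' are mean-imputed per marker; zero-variance (monomorphic) markers are
#' skipped.
#'
#' @param G strains x markers matrix coded 0/1 (`NA` allowed).
#' @return symmetric PSD kinship matrix with attribute `n_markers` (markers
#'   actually used).
#' @export
kinship <- function(G) {
  stopifnot(is.matrix(G), nrow(G) >= 2, ncol(G) >= 1)
  G <- apply(G, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  p <- colMeans(G)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  M <- 2 * G - 1                # -1/1 inbred coding
  W <- sweep(M, 2, 2 * p - 1)   # center by 2p - 1
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  K <- (K + t(K)) / 2
  attr(K, "n_markers") <- sum(poly)
  K
}
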