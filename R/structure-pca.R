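# PCA on standardized genotypes.

#' Principal component analysis of a genotype matrix
#'
#' Each SNP column is centered by `2 p` and scaled by `sqrt(2 p (1 - p))`
#' with `p` estimated from non-missing calls; missing entries contribute 0
#' after centering.  Scores come from the spectral decomposition of the
#' sample-by-sample cross-product of the standardized matrix (equivalent to
#' the SVD of the standardized matrix itself).
#'
#' @param geno a post-QC [genotype_matrix()].
#' @param k number of components, `k <= min(n_samples, n_snps)`.
#' @return list of class `pca_result`: `scores` (n x k, unit-norm columns),
#'   `eigenvalues` (k, non-increasing; variance explained per component on
#'   the per-SNP scale), `n_monomorphic` excluded SNPs.
#' @export
pca <- function(geno, k = 10L) {
  g <- geno$calls
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  n_mono <- sum(!poly)
  if (n_mono > 0L) message(n_mono, " monomorphic SNP(s) excluded from PCA")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  n <- nrow(g); m <- ncol(g)
  if (k > min(n, m)) stop("k exceeds min(n_samples, n_snps)")
  x <- sweep(g, 2L, 2 * p)
  x <- sweep(x, 2L, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  gram <- tcrossprod(x) / m
  eig <- eigen(gram, symmetric = TRUE)
  scores <- eig$vectors[, seq_len(k), drop = FALSE]
  rownames(scores) <- geno$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, eigenvalues = eig$values[seq_len(k)],
                 n_monomorphic = n_mono),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n  leading eigenvalues:",
      paste(signif(head(x$eigenvalues, 5L), 4L), collapse = ", "), "\n")
  invisible(x)
}
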