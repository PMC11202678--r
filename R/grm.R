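#' VanRaden genomic relationship matrix
#'
#' Computes the first VanRaden relationship matrix
#' \deqn{A = \frac{Z Z'}{2 \sum_j p_j (1 - p_j)}}
#' where the dosage column for marker j is centered by twice its allele
#' frequency, \eqn{Z_{ij} = d_{ij} - 2 p_j}. Column centering forces zero
#' row sums; the matrix is symmetric and positive semidefinite.
#'
#' @param g a complete (no missing calls) [geno_matrix()] or dosage matrix.
#' @param p optional allele frequencies to center by; defaults to the
#'   frequencies observed in `g`. Supplying the full-panel frequencies keeps
#'   the kinship identical across cross-validation subsets.
#' @return a `grm` object: the relationship matrix with attributes `p`
#'   (centering frequencies) and `denom` (the scaling \eqn{2\sum p(1-p)}).
#' @export
vanraden_grm <- function(g, p = NULL) {
  dosage <- if (inherits(g, "geno_matrix")) g$dosage else as.matrix(g)
  if (anyNA(dosage))
    stop("vanraden_grm requires a complete matrix; run impute_missing() first")
  if (is.null(p)) p <- marker_freq(dosage)
  if (length(p) != ncol(dosage))
    stop("length(p) must equal the number of markers")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("vanraden_grm: all markers monomorphic (zero denominator)")
  Z <- sweep(dosage, 2L, 2 * p, "-")
  A <- tcrossprod(Z) / denom
  A <- (A + t(A)) / 2
  structure(A, p = p, denom = denom, class = c("grm", "matrix"))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("VanRaden relationship matrix: %d lines, denominator %.4f\n",
              nrow(x), attr(x, "denom")))
  cat(sprintf("  diag range [%.3f, %.3f], mean diag %.3f\n",
              min(diag(x)), max(diag(x)), mean(diag(x))))
  invisible(x)
}

#' Principal component analysis of a genotype panel
#'
#' Singular value decomposition of the column-centered dosage matrix,
#' returning line scores and the fraction of genetic variance carried by
#' each component. The components coincide (up to the GRM denominator) with
#' the eigenvectors of the VanRaden matrix, since both derive from
#' \eqn{Z Z'}.
#'
#' @param g a complete [geno_matrix()] or dosage matrix.
#' @param k number of components to return.
#' @return list with `scores` (lines x k), `var_fraction` (length k,
#'   non-increasing), and `sdev` (all singular values / sqrt(n-1)).
#' @export
pca_genotypes <- function(g, k = 2L) {
  dosage <- if (inherits(g, "geno_matrix")) g$dosage else as.matrix(g)
  if (anyNA(dosage)) stop("pca_genotypes requires a complete matrix")
  n <- nrow(dosage)
  if (n < k + 1L) stop("need at least k + 1 lines")
  Z <- scale(dosage, center = TRUE, scale = FALSE)
  sv <- svd(Z, nu = min(n, ncol(Z)), nv = 0)
  tol <- max(dim(Z)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (k > rank)
    stop(sprintf("k = %d exceeds the matrix rank %d", k, rank))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(dosage)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       var_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2),
       sdev = sv$d / sqrt(n - 1))
}
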