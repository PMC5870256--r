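#' Genotype principal components for ancestry adjustment
#'
#' Computes principal components of the (optionally LD-pruned) dosage matrix
#' with Patterson normalization: missing dosages are mean-imputed per
#' variant, then each variant is centered by `2p` and scaled by
#' `sqrt(2p(1-p))` where `p` is the alt-allele frequency estimate.
#' Eigendecomposition is taken of the sample-by-sample cross-product; the
#' sign of each component is fixed so that its largest-magnitude variant
#' loading is positive, making downstream regressions reproducible.
#'
#' @param g A `genotype_matrix`.
#' @param pruned_ids Optional character vector of variant IDs to use
#'   (typically the output of [ld_prune()]); `NULL` uses all variants.
#' @param K Number of components to return.
#' @return An object of class `pc_matrix`: list with `scores` (individuals x
#'   K, rownames sample IDs), `explained_variance` (fraction per component),
#'   and `K`.
#' @export
compute_pcs <- function(g, pruned_ids = NULL, K = 10) {
  if (K < 1) stop("K must be at least 1")
  if (!is.null(pruned_ids)) {
    if (!length(pruned_ids)) stop("pruned variant set is empty")
    g <- g[, pruned_ids]
  }
  X <- g$dosages
  storage.mode(X) <- "double"
  p <- colMeans(X, na.rm = TRUE) / 2
  ok <- !is.na(p) & p > 0 & p < 1
  if (!any(ok)) stop("no polymorphic variants available for PCA")
  X <- X[, ok, drop = FALSE]
  p <- p[ok]
  # mean-impute, center by 2p, Patterson scale
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    xj[is.na(xj)] <- 2 * p[j]
    X[, j] <- (xj - 2 * p[j]) / sqrt(2 * p[j] * (1 - p[j]))
  }
  n <- nrow(X)
  A <- tcrossprod(X)
  eig <- eigen(A, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  tot <- sum(vals)
  if (tot <= 0) stop("zero-variance matrix: all individuals identical")
  rank <- sum(vals > tot * 1e-12)
  if (K > rank)
    stop("K = ", K, " exceeds the rank (", rank, ") of the normalized matrix")
  d <- sqrt(vals[seq_len(K)])
  scores <- eig$vectors[, seq_len(K), drop = FALSE] %*% diag(d, K)
  # deterministic sign: largest-magnitude loading positive
  loadings <- crossprod(X, eig$vectors[, seq_len(K), drop = FALSE])
  for (k in seq_len(K)) {
    lk <- loadings[, k]
    s <- sign(lk[which.max(abs(lk))])
    if (s < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- g$samples$id
  colnames(scores) <- paste0("PC", seq_len(K))
  structure(list(scores = scores,
                 explained_variance = vals[seq_len(K)] / tot,
                 K = K),
            class = "pc_matrix")
}

#' @export
print.pc_matrix <- function(x, ...) {
  cat("pc_matrix:", nrow(x$scores), "individuals x", x$K, "components\n")
  cat("  explained variance:",
      paste(sprintf("%.3f", x$explained_variance[seq_len(min(5, x$K))]),
            collapse = " "),
      if (x$K > 5) "..." else "", "\n")
  invisible(x)
}
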