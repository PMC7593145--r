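# Shape PCA with broken-stick component selection.

#' Principal component analysis with broken-stick significance
#'
#' Eigen-decomposes the covariance of the row-centered shape matrix. The
#' number of interpretable components is the longest prefix of components
#' whose observed variance proportion exceeds the broken-stick expectation
#' `b_j = (1/p) * sum_{k=j}^{p} 1/k` over the `p` nonzero components.
#'
#' @param Y N x p matrix (rows = species mean shapes).
#' @param tol relative eigenvalue threshold below which components are
#'   treated as numerically zero.
#' @return a `shape_pca`: `scores`, `rotation`, `eigenvalues`,
#'   `percent` (variance percentages), `broken_stick` (expected
#'   proportions), `n_significant`, `center`.
#' @export
pca_broken_stick <- function(Y, tol = 1e-10) {
  Y <- as.matrix(Y)
  stop_if(nrow(Y) < 3, "PCA needs at least 3 observations")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  sv <- svd(Yc)
  ev <- sv$d^2 / (nrow(Y) - 1)
  nz <- which(ev > tol * ev[1])
  ev <- ev[nz]
  p <- length(ev)
  prop <- ev / sum(ev)
  bs <- rev(cumsum(1 / rev(seq_len(p)))) / p
  below <- which(prop <= bs)
  n_sig <- if (length(below) == 0) p else below[1] - 1L
  scores <- Yc %*% sv$v[, nz, drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(p))
  structure(list(scores = scores, rotation = sv$v[, nz, drop = FALSE],
                 eigenvalues = ev, percent = 100 * prop, broken_stick = bs,
                 n_significant = n_sig, center = ctr),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  n <- min(length(x$percent), 6)
  cat(sprintf("shape PCA: %d nonzero components, %d significant (broken stick)\n",
              length(x$percent), x$n_significant))
  cat("  % variance:", paste(sprintf("%.2f", x$percent[seq_len(n)]),
                             collapse = ", "),
      if (length(x$percent) > n) "..." else "", "\n")
  invisible(x)
}

#' Project secondary configurations into an existing shape PCA
#'
#' Applies the stored centering and rotation, so e.g. individual specimen
#' configurations (aligned as their species means were) can be plotted in
#' the species-mean morphospace.
#'
#' @param object a `shape_pca`.
#' @param newdata matrix with the same columns as the PCA input.
#' @param ... unused.
#' @return score matrix for `newdata`.
#' @export
predict.shape_pca <- function(object, newdata, ...) {
  out <- sweep(as.matrix(newdata), 2, object$center) %*% object$rotation
  colnames(out) <- paste0("PC", seq_len(ncol(out)))
  out
}
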