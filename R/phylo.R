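# Phylogenetic covariance machinery and multivariate phylogenetic signal.

#' Phylogenetic covariance matrix and its whitening transform
#'
#' `C[i, j]` is the shared root-to-MRCA branch length of tips i and j
#' (diagonal: root-to-tip length). `P = Lambda^{-1/2} U'` from the
#' eigendecomposition `C = U Lambda U'`, so that `P C P' = I`; premultiplying
#' data and design matrices by `P` turns generalized least squares under
#' Brownian motion into ordinary least squares.
#'
#' @param tree an `ape::phylo` with positive branch lengths.
#' @return list with `C` (N x N, tip-labelled), `P` (N x N), and `Cinv`.
#' @export
phylo_cov <- function(tree) {
  C <- ape::vcv(tree)
  eig <- eigen(C, symmetric = TRUE)
  if (min(eig$values) <= 1e-12 * max(eig$values))
    stop("phylogenetic covariance is numerically singular (condition ",
         format(max(eig$values) / max(min(eig$values), .Machine$double.xmin)),
         ")", call. = FALSE)
  P <- diag(1 / sqrt(eig$values)) %*% t(eig$vectors)
  Cinv <- eig$vectors %*% diag(1 / eig$values) %*% t(eig$vectors)
  list(C = C, P = P, Cinv = Cinv, tips = rownames(C))
}

kmult_stat <- function(Y, Cinv, ones, denom_expect) {
  N <- nrow(Y)
  a_hat <- drop(crossprod(ones, Cinv %*% Y)) / sum(Cinv)
  Yc <- sweep(Y, 2, a_hat)
  num <- sum(Yc^2)
  den <- sum(Yc * (Cinv %*% Yc))
  if (den <= 0) stop("undefined statistic: zero phylogenetically corrected variance",
                     call. = FALSE)
  (num / den) / denom_expect
}

#' Multivariate phylogenetic signal (K statistic)
#'
#' The multivariate generalization of Blomberg's K: the ratio of observed to
#' phylogenetically expected trait variance, scaled so that data evolving by
#' Brownian motion on the given tree have an expectation of 1. Values above
#' 1 indicate more phylogenetic signal than Brownian motion predicts, values
#' below 1 less. Significance is assessed by randomly shuffling species
#' across the tips.
#'
#' @param Y N x p matrix of species values (rows named/ordered by the tree's
#'   tip labels).
#' @param tree `ape::phylo`.
#' @param n_perm permutations for the significance test (the observed value
#'   counts as one of them); 0 skips the test.
#' @param seed RNG seed for the permutations.
#' @return a `kmult` object: `K`, `p`, `n_perm`, `perms`.
#' @export
kmult <- function(Y, tree, n_perm = 1000, seed = 1) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  stop_if(N < 4, "K requires at least 4 species")
  if (!is.null(rownames(Y))) {
    stop_if(!setequal(rownames(Y), tree$tip.label),
            "row names of Y must match the tree's tip labels")
    Y <- Y[tree$tip.label, , drop = FALSE]
  }
  pc <- phylo_cov(tree)
  ones <- rep(1, N)
  denom_expect <- (sum(diag(pc$C)) - N / sum(pc$Cinv)) / (N - 1)
  K_obs <- kmult_stat(Y, pc$Cinv, ones, denom_expect)
  p <- NA_real_; perms <- numeric(0)
  if (n_perm > 0) {
    set.seed(seed)
    perms <- vapply(seq_len(n_perm - 1), function(i)
      kmult_stat(Y[sample(N), , drop = FALSE], pc$Cinv, ones, denom_expect), 0)
    p <- perm_pvalue(K_obs, perms, "upper")
  }
  structure(list(K = K_obs, p = p, n_perm = n_perm, perms = perms),
            class = "kmult")
}

#' @export
print.kmult <- function(x, ...) {
  cat(sprintf("multivariate phylogenetic signal: K = %.4f", x$K))
  if (!is.na(x$p)) cat(sprintf(", p = %.4g (%d permutations)", x$p, x$n_perm))
  cat("\n")
  invisible(x)
}
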