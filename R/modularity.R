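# Covariance-ratio modularity in a phylogenetic context.

cr_statistic <- function(S, module, pairs) {
  crs <- apply(pairs, 1, function(pr) {
    A <- which(module == pr[1]); B <- which(module == pr[2])
    SAB <- S[A, B, drop = FALSE]
    SA <- S[A, A, drop = FALSE]; diag(SA) <- 0
    SB <- S[B, B, drop = FALSE]; diag(SB) <- 0
    sqrt(sum(SAB^2) / sqrt(sum(SA^2) * sum(SB^2)))
  })
  mean(crs)
}

#' Covariance-ratio test of modularity
#'
#' Quantifies whether covariation between putative landmark modules (here
#' the four girdle bones) is weak relative to covariation within them, on
#' phylogenetically transformed residuals (data whitened by the tree's
#' covariance after removing the GLS root estimate). The covariance ratio
#' for a module pair is
#' `CR = sqrt(tr(S_AB S_BA) / sqrt(tr(S_A* S_A*) tr(S_B* S_B*)))`,
#' with the within-module diagonals zeroed; multi-module CR is the mean over
#' pairs. CR < 1 indicates modularity. The null distribution reassigns whole
#' landmarks (xyz triples together) to modules of the same sizes; low CR is
#' the rejection direction, so `p` is the fraction of permuted CR values at
#' or below the observed one (observed included).
#'
#' @param Y N x 3k shape matrix, columns landmark-major (x1, y1, z1, x2, ...).
#' @param partition factor/character of length k assigning each landmark to
#'   a module; every module needs >= 2 landmarks.
#' @param tree `ape::phylo` or `NULL` (no phylogenetic transform).
#' @param n_perm permutations (observed included).
#' @param seed RNG seed.
#' @return a `modularity_cr` object: `CR`, `p`, `pairwise` (CR per module
#'   pair), `n_perm`.
#' @export
modularity_cr <- function(Y, partition, tree = NULL, n_perm = 1000, seed = 1) {
  Y <- as.matrix(Y)
  k <- length(partition)
  stop_if(ncol(Y) != 3 * k,
          "partition must have one entry per landmark (3 columns each)")
  partition <- as.character(partition)
  sizes <- table(partition)
  stop_if(length(sizes) < 2, "need at least 2 modules")
  stop_if(any(sizes < 2), "every module needs at least 2 landmarks")

  if (!is.null(tree)) {
    pc <- phylo_cov(tree)
    if (!is.null(rownames(Y))) Y <- Y[tree$tip.label, , drop = FALSE]
    ones <- rep(1, nrow(Y))
    a_hat <- drop(crossprod(ones, pc$Cinv %*% Y)) / sum(pc$Cinv)
    R <- pc$P %*% sweep(Y, 2, a_hat)
  } else {
    R <- sweep(Y, 2, colMeans(Y))
  }
  S <- crossprod(R) / (nrow(Y) - 1)

  mods <- sort(unique(partition))
  pairs <- t(utils::combn(mods, 2))
  col_module <- rep(partition, each = 3)
  cr_obs <- cr_statistic(S, col_module, pairs)
  pairwise <- stats::setNames(
    apply(pairs, 1, function(pr) cr_statistic(S, col_module,
                                              matrix(pr, 1))),
    paste(pairs[, 1], pairs[, 2], sep = ":"))

  set.seed(seed)
  perms <- vapply(seq_len(n_perm - 1), function(b) {
    newpart <- sample(partition)
    cr_statistic(S, rep(newpart, each = 3), pairs)
  }, 0)
  p <- perm_pvalue(cr_obs, perms, "lower")
  structure(list(CR = cr_obs, p = p, pairwise = pairwise, n_perm = n_perm),
            class = "modularity_cr")
}

#' @export
print.modularity_cr <- function(x, ...) {
  cat(sprintf("covariance-ratio modularity: CR = %.4f, p = %.4g (%d permutations)\n",
              x$CR, x$p, x$n_perm))
  invisible(x)
}
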