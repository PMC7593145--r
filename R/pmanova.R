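# Phylogenetic MANOVA via GLS transform + residual randomization (RRPP),
# and size-corrected pairwise comparisons of group mean shapes.

rss_of <- function(Q, Y) sum((Q %*% Y)^2)

# Residual-maker (annihilator) matrix of a design X.
resid_projector <- function(X) {
  q <- qr(X)
  Qm <- diag(nrow(X)) - tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
  Qm
}

#' Phylogenetic MANOVA with residual randomization
#'
#' Fits `shape ~ logCS + group + logCS:group` by generalized least squares
#' under Brownian motion (data and design premultiplied by the whitening
#' transform of the phylogenetic covariance), with type-II sums of squares:
#' each main effect is tested against the model containing the other main
#' effect, the interaction against the full main-effects model. Sums of
#' squares are summed over all shape coordinates. Significance is assessed
#' by RRPP: rows of the reduced-model residuals are permuted, added back to
#' the reduced-model fitted values, and the term's F is recomputed; the
#' observed F counts as one permutation.
#'
#' @param Y N x p shape matrix (rows ordered/named by tip labels).
#' @param logCS numeric covariate (log centroid size).
#' @param group factor with the locomotor groups.
#' @param tree `ape::phylo`, or `NULL` for an identity phylogenetic
#'   covariance (ordinary MANOVA; used by the OLS cross-checks).
#' @param n_perm permutations (observed included); 0 skips p-values.
#' @param seed RNG seed.
#' @return a `pmanova` object whose `table` is a data frame with rows
#'   logCS, group, logCS:group, Residuals, Total and columns Df, SS, MS,
#'   Rsq, F, p.
#' @export
pgls_manova <- function(Y, logCS, group, tree = NULL, n_perm = 1000, seed = 1) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  group <- droplevels(as.factor(group))
  stop_if(length(logCS) != N || length(group) != N,
          "logCS and group must match the rows of Y")
  if (!is.null(tree) && !is.null(rownames(Y))) {
    stop_if(!setequal(rownames(Y), tree$tip.label),
            "row names of Y must match the tree's tip labels")
    ord <- match(tree$tip.label, rownames(Y))
    Y <- Y[ord, , drop = FALSE]; logCS <- logCS[ord]; group <- group[ord]
  }
  P <- if (is.null(tree)) diag(N) else phylo_cov(tree)$P

  x_size <- logCS - mean(logCS)
  G <- stats::model.matrix(~group)[, -1, drop = FALSE]
  df_g <- ncol(G)
  designs <- list(
    int   = matrix(1, N, 1),
    size  = cbind(1, x_size),
    group = cbind(1, G),
    main  = cbind(1, x_size, G),
    full  = cbind(1, x_size, G, x_size * G))
  full_rank <- qr(P %*% designs$full)$rank
  aliased <- full_rank < ncol(designs$full)
  stop_if(N <= ncol(designs$full),
          "full model is not estimable: need N > total model df")

  Qs <- lapply(designs, function(X) resid_projector(P %*% X))
  Yt <- P %*% Y
  rssv <- vapply(Qs, rss_of, 0, Y = Yt)

  df_res <- N - ncol(designs$full)
  terms <- data.frame(
    row.names = c("logCS", "group", "logCS:group"),
    Df = c(1, df_g, df_g),
    SS = c(rssv["group"] - rssv["main"],
           rssv["size"] - rssv["main"],
           rssv["main"] - rssv["full"]))
  rss_full <- rssv["full"]; ss_tot <- rssv["int"]
  terms$MS <- terms$SS / terms$Df
  terms$Rsq <- terms$SS / ss_tot
  terms$F <- terms$MS / (rss_full / df_res)
  if (rss_full <= 1e-12 * ss_tot) terms$F <- rep(Inf, 3)

  terms$p <- NA_real_
  if (n_perm > 0 && is.finite(terms$F[1])) {
    set.seed(seed)
    red_of <- c(logCS = "group", group = "size", `logCS:group` = "main")
    hi_of <- c(logCS = "main", group = "main", `logCS:group` = "full")
    # reduced-model fits for RRPP
    fits <- lapply(red_of, function(nm) {
      Qr <- Qs[[nm]]
      E <- Qr %*% Yt
      list(fitted = Yt - E, E = E)
    })
    perm_idx <- replicate(n_perm - 1, sample(N))
    perm_F <- matrix(NA_real_, n_perm - 1, 3)
    for (b in seq_len(n_perm - 1)) {
      ix <- perm_idx[, b]
      for (tm in 1:3) {
        red <- red_of[tm]; hi <- hi_of[tm]
        Yb <- fits[[tm]]$fitted + fits[[tm]]$E[ix, , drop = FALSE]
        ss <- rss_of(Qs[[red]], Yb) - rss_of(Qs[[hi]], Yb)
        rf <- rss_of(Qs$full, Yb)
        perm_F[b, tm] <- (ss / terms$Df[tm]) / (rf / df_res)
      }
    }
    terms$p <- vapply(1:3, function(tm)
      perm_pvalue(terms$F[tm], perm_F[, tm], "upper"), 0)
  }

  table <- rbind(terms,
                 Residuals = data.frame(Df = df_res, SS = rss_full,
                                        MS = rss_full / df_res,
                                        Rsq = rss_full / ss_tot, F = NA, p = NA),
                 Total = data.frame(Df = N - 1, SS = ss_tot, MS = NA,
                                    Rsq = NA, F = NA, p = NA))
  structure(list(table = table, n_perm = n_perm, aliased = aliased,
                 ss_total = ss_tot, designs = designs, P = P),
            class = "pmanova")
}

#' @export
print.pmanova <- function(x, digits = 5, ...) {
  cat("phylogenetic MANOVA (GLS transform, type-II SS, RRPP)\n")
  tb <- x$table
  tb$SS <- signif(tb$SS, digits); tb$MS <- signif(tb$MS, digits)
  tb$Rsq <- round(tb$Rsq, 5); tb$F <- signif(tb$F, digits)
  print(tb)
  if (x$aliased) cat("warning: rank-deficient full model (aliased terms)\n")
  invisible(x)
}

#' Size-corrected pairwise comparisons of group mean shapes
#'
#' On phylogenetically transformed data, fits `shape ~ logCS + group`,
#' evaluates least-squares group means at the grand-mean log centroid size,
#' and tests each pairwise Euclidean distance between group means by RRPP
#' over the null model `shape ~ logCS` (residuals of the size-only model
#' permuted and added back to its fitted values).
#'
#' @inheritParams pgls_manova
#' @return a `pairwise_shape` object with symmetric matrices `d` (distances
#'   between LS means) and `p`.
#' @export
pairwise_groups <- function(Y, logCS, group, tree = NULL, n_perm = 1000,
                            seed = 1) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  group <- droplevels(as.factor(group))
  if (!is.null(tree) && !is.null(rownames(Y))) {
    ord <- match(tree$tip.label, rownames(Y))
    Y <- Y[ord, , drop = FALSE]; logCS <- logCS[ord]; group <- group[ord]
  }
  tab <- table(group)
  if (any(tab < 2)) {
    warning("excluding singleton groups: ",
            paste(names(tab)[tab < 2], collapse = ", "))
    keep <- group %in% names(tab)[tab >= 2]
    Y <- Y[keep, , drop = FALSE]; logCS <- logCS[keep]
    group <- droplevels(group[keep])
    N <- nrow(Y)
  }
  P <- if (is.null(tree)) diag(N) else phylo_cov(tree)$P
  x_size <- logCS - mean(logCS)
  G <- stats::model.matrix(~group)
  lv <- levels(group); ng <- length(lv)
  # evaluation rows: each group at the grand-mean log centroid size
  L <- cbind(stats::model.matrix(~factor(lv, levels = lv)), 0)
  Xt_fit <- P %*% cbind(G, x_size)
  qr_fit <- qr(Xt_fit)

  lsmeans_of <- function(Yt) {
    B <- qr.coef(qr_fit, Yt)
    B[is.na(B)] <- 0
    L %*% B
  }
  dist_mat <- function(M) as.matrix(stats::dist(M))

  Yt <- P %*% Y
  mu <- lsmeans_of(Yt)
  d_obs <- dist_mat(mu)
  dimnames(d_obs) <- list(lv, lv)

  # RRPP over the size-only null model
  Xnull <- P %*% cbind(1, x_size)
  Qn <- resid_projector(Xnull)
  E <- Qn %*% Yt
  Fit <- Yt - E
  set.seed(seed)
  hits <- matrix(0, ng, ng)
  for (b in seq_len(n_perm - 1)) {
    Yb <- Fit + E[sample(N), , drop = FALSE]
    db <- dist_mat(lsmeans_of(Yb))
    hits <- hits + (db >= d_obs - 1e-15)
  }
  p <- (1 + hits) / n_perm
  diag(p) <- NA
  dimnames(p) <- list(lv, lv)
  structure(list(d = d_obs, p = p, n_perm = n_perm, groups = lv),
            class = "pairwise_shape")
}

#' @export
print.pairwise_shape <- function(x, ...) {
  cat("pairwise LS-mean shape distances (lower) and RRPP p-values (upper)\n")
  m <- x$d
  m[upper.tri(m)] <- x$p[upper.tri(m)]
  print(round(m, 4))
  invisible(x)
}
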