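test_that("phylogenetic covariance encodes shared branch lengths", {
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  pc <- phylo_cov(star)
  expect_equal(unname(pc$C), diag(6))
  expect_equal(unname(pc$P %*% pc$C %*% t(pc$P)), diag(6), tolerance = 1e-9)

  tr <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,c:1);")
  C <- phylo_cov(tr)$C
  expect_equal(C["a", "b"], 0.5)
  expect_equal(C["a", "a"], 1)
  expect_equal(C["a", "c"], 0)

  for (s in 1:5) {
    rt <- sim_tree(10, seed = s)
    pc <- phylo_cov(rt)
    expect_equal(unname(pc$P %*% pc$C %*% t(pc$P)), diag(10), tolerance = 1e-9)
  }
})

test_that("K equals 1 exactly on a star phylogeny", {
  star <- ape::stree(8, "star")
  star$edge.length <- rep(1, 8)
  set.seed(21)
  Y <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(star$tip.label, NULL))
  expect_equal(kmult(Y, star, n_perm = 0)$K, 1, tolerance = 1e-12)
})

test_that("the multivariate K reduces to Blomberg's K for one trait", {
  skip_if_not_installed("picante")
  for (s in 1:3) {
    tr <- sim_tree(16, seed = s)
    set.seed(s)
    y <- stats::setNames(as.vector(girdlemorph:::sim_bm_tips(tr, 1, 1)),
                         tr$tip.label)
    K_ours <- kmult(matrix(y, ncol = 1, dimnames = list(names(y), NULL)),
                    tr, n_perm = 0)$K
    K_ref <- picante::Kcalc(y, tr, checkdata = TRUE)
    expect_equal(K_ours, as.numeric(as.matrix(K_ref)), tolerance = 1e-8)
  }
})

test_that("K is invariant to rotation and scaling of trait space", {
  tr <- sim_tree(12, seed = 31)
  set.seed(31)
  Y <- girdlemorph:::sim_bm_tips(tr, 1, 6)
  rownames(Y) <- tr$tip.label
  K0 <- kmult(Y, tr, n_perm = 0)$K
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  expect_equal(kmult(Y %*% Q, tr, n_perm = 0)$K, K0, tolerance = 1e-9)
  expect_equal(kmult(Y * 7.3, tr, n_perm = 0)$K, K0, tolerance = 1e-9)
})

test_that("permutation p-values are seeded and floored at 1/n_perm", {
  tr <- sim_tree(10, seed = 32)
  set.seed(32)
  Y <- girdlemorph:::sim_bm_tips(tr, 1, 4)
  rownames(Y) <- tr$tip.label
  a <- kmult(Y, tr, n_perm = 99, seed = 5)
  b <- kmult(Y, tr, n_perm = 99, seed = 5)
  expect_identical(a$p, b$p)
  expect_gte(a$p, 1 / 99)
})

test_that("the GLS MANOVA reproduces a brute-force OLS decomposition", {
  # star phylogeny = identity covariance: must match ordinary least squares
  rss_lm <- function(f, d) sum(stats::resid(stats::lm(f, data = d))^2)
  for (s in 1:4) {
    set.seed(s)
    n <- c(12, 14, 15, 12)[s]
    d <- data.frame(g = factor(rep_len(c("a", "b", "c"), n)), x = rnorm(n))
    p <- 1 + (s %% 3)
    Y <- matrix(rnorm(n * p), n, p)
    d$xs <- d$x - mean(d$x)
    fit <- pgls_manova(Y, d$x, d$g, tree = NULL, n_perm = 0)
    rss_of <- function(f) sum(vapply(seq_len(p), function(j) {
      dd <- d; dd$y <- Y[, j]; rss_lm(f, dd)
    }, 0))
    SS_x <- rss_of(y ~ g) - rss_of(y ~ xs + g)
    SS_g <- rss_of(y ~ xs) - rss_of(y ~ xs + g)
    SS_i <- rss_of(y ~ xs + g) - rss_of(y ~ xs * g)
    RSSf <- rss_of(y ~ xs * g)
    df_res <- n - 6
    expect_equal(fit$table[c("logCS", "group", "logCS:group"), "SS"],
                 c(SS_x, SS_g, SS_i), tolerance = 1e-8)
    expect_equal(fit$table["Residuals", "SS"], RSSf, tolerance = 1e-8)
    expect_equal(fit$table[c("logCS", "group", "logCS:group"), "F"],
                 c(SS_x / 1, SS_g / 2, SS_i / 2) / (RSSf / df_res),
                 tolerance = 1e-8)
    expect_equal(fit$table["Total", "SS"], rss_of(y ~ 1), tolerance = 1e-8)
  }
})

test_that("zero-residual data flag infinite F", {
  set.seed(41)
  n <- 18
  g <- factor(rep_len(letters[1:2], n))
  x <- rnorm(n)
  X <- stats::model.matrix(~ I(x - mean(x)) * g)
  Y <- X %*% matrix(rnorm(ncol(X) * 2), ncol = 2)   # exact fitted values
  fit <- pgls_manova(Y, x, g, tree = NULL, n_perm = 100)
  expect_true(all(is.infinite(fit$table[1:3, "F"])))
})

test_that("ANOVA table satisfies its accounting identities", {
  sim <- simulate_fixed_dataset(n_species = 24, seed = 6, group_effect = 0.4)
  fit <- pgls_manova(sim$Y, sim$logCS, sim$group, sim$tree, n_perm = 99,
                     seed = 2)
  tb <- fit$table
  # under type-II sums of squares the term SS need not add to the total in a
  # non-orthogonal design; the df decomposition and R-squared scaling must
  expect_equal(sum(tb[c("logCS", "group", "logCS:group", "Residuals"), "Df"]),
               tb["Total", "Df"])
  expect_true(all(tb$SS[1:4] >= -1e-12))
  expect_lte(sum(tb[c("logCS", "group", "logCS:group", "Residuals"), "Rsq"]),
             1 + 1e-9)
  expect_equal(tb$Rsq[1:4], tb$SS[1:4] / tb["Total", "SS"], tolerance = 1e-12)
})

test_that("pairwise group tests: geometry of the distance matrix and separation", {
  sim <- simulate_fixed_dataset(n_species = 24, seed = 7, group_effect = 0)
  pw <- pairwise_groups(sim$Y, sim$logCS, sim$group, sim$tree, n_perm = 99,
                        seed = 3)
  expect_equal(pw$d, t(pw$d))
  expect_true(all(diag(pw$d) == 0))
  expect_true(all(pw$p[upper.tri(pw$p)] >= 1 / 99))

  # displace one group far away (identity covariance so the displacement
  # stays group-aligned): its pairwise p-values hit the floor
  Y2 <- sim$Y
  shift <- which(sim$group == levels(sim$group)[1])
  Y2[shift, ] <- Y2[shift, ] + 50 * max(abs(Y2))
  pw2 <- pairwise_groups(Y2, sim$logCS, sim$group, tree = NULL, n_perm = 100,
                         seed = 3)
  lv <- levels(sim$group)[1]
  expect_true(all(pw2$p[lv, colnames(pw2$p) != lv] == 1 / 100))
})

test_that("broken-stick PCA matches its closed form and finds planted axes", {
  b3 <- rev(cumsum(1 / 3:1)) / 3
  expect_equal(b3, c(11 / 18, 5 / 18, 2 / 18))

  set.seed(51)
  n <- 40
  u <- girdlemorph:::unit_vec(rnorm(10))
  Y <- (rnorm(n, sd = 10) %o% u) + matrix(rnorm(n * 10, sd = 0.1), n, 10)
  pc <- pca_broken_stick(Y)
  expect_identical(pc$n_significant, 1L)
  expect_equal(sum(pc$percent), 100, tolerance = 1e-9)
  expect_equal(sum(pc$broken_stick), 1, tolerance = 1e-12)
  # projection of the training data reproduces the scores
  expect_equal(predict(pc, Y), pc$scores, tolerance = 1e-9)
})

test_that("covariance-ratio statistic matches closed forms", {
  cr_stat <- girdlemorph:::cr_statistic
  # block-diagonal covariance (within-module structure, none between): CR = 0
  blk <- matrix(c(1, 0.5, 0.5, 1), 2)
  S <- rbind(cbind(blk, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), blk))
  module <- c("A", "A", "B", "B")
  pairs <- matrix(c("A", "B"), 1)
  expect_equal(cr_stat(S, module, pairs), 0)
  # equal off-diagonal covariances: CR = sqrt(2)
  S2 <- matrix(0.3, 4, 4); diag(S2) <- 1
  expect_equal(cr_stat(S2, module, pairs), sqrt(2), tolerance = 1e-12)
})

test_that("strong within-module structure drives the CR p to its floor", {
  set.seed(61)
  n <- 50; k <- 16
  module <- rep(c("A", "B"), each = 8)
  fA <- rnorm(n); fB <- rnorm(n)
  Y <- matrix(0, n, 3 * k)
  for (j in seq_len(k)) {
    f <- if (module[j] == "A") fA else fB
    Y[, 3 * (j - 1) + 1:3] <- f %o% rep(1, 3) + matrix(rnorm(n * 3, sd = 0.05), n, 3)
  }
  res <- modularity_cr(Y, module, tree = NULL, n_perm = 100, seed = 4)
  expect_lt(res$CR, 1)
  expect_equal(res$p, 1 / 100)
  expect_error(modularity_cr(Y, rep(c("A", "B", "C", "D"), 4), tree = NULL),
               NA)
  expect_error(modularity_cr(Y, c("A", rep("B", 15)), tree = NULL),
               "at least 2 landmarks")
})
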