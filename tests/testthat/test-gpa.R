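test_that("similarity-transformed copies align to a single shape", {
  set.seed(11)
  tpl <- the_template()
  copies <- replicate(4, transformed_copy(tpl$config), simplify = FALSE)
  fit <- gpa(copies, slide = FALSE)
  expect_true(fit$converged)
  expect_lt(max(fit$procrustes_distances), 1e-9)
  d12 <- procrustes_distance(fit$aligned[, , 1], fit$aligned[, , 2])
  expect_lt(d12, 1e-9)
})

test_that("aligned configurations are centered with unit centroid size", {
  set.seed(12)
  tpl <- the_template()
  copies <- replicate(3, transformed_copy(tpl$config, noise_sd = 0.05),
                      simplify = FALSE)
  fit <- gpa(copies, slide = TRUE, max_iter = 6)
  for (i in 1:3) {
    m <- fit$aligned[, , i]
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_equal(sqrt(sum(m^2)), 1, tolerance = 1e-9)
  }
  # consensus equals the coordinate-wise mean (after normalization)
  cons <- girdlemorph:::center_scale(apply(fit$aligned, c(1, 2), mean))
  expect_lt(max(abs(cons - fit$consensus)), 1e-9)
  # original centroid sizes retained
  expect_equal(fit$centroid_sizes, vapply(copies, centroid_size, 0))
})

test_that("GPA is invariant to pre-transforming any input configuration", {
  set.seed(13)
  tpl <- the_template()
  base <- replicate(3, transformed_copy(tpl$config, noise_sd = 0.03),
                    simplify = FALSE)
  fit1 <- gpa(base, slide = FALSE)
  moved <- base
  moved[[2]] <- transformed_copy(moved[[2]])
  fit2 <- gpa(moved, slide = FALSE)
  expect_equal(fit1$procrustes_distances, fit2$procrustes_distances,
               tolerance = 1e-8)
})

test_that("sliding reduces bending energy and never moves fixed landmarks", {
  set.seed(14)
  tpl <- the_template()
  copies <- replicate(3, transformed_copy(tpl$config, noise_sd = 0.05),
                      simplify = FALSE)
  fit <- gpa(copies, slide = TRUE, max_iter = 8)
  expect_true(all(diff(fit$bending_energy_trace) <= 1e-12))

  # the sliding step itself leaves fixed landmarks and curve endpoints
  # exactly where they were
  cons <- fit$consensus
  Bmat <- tps_bending_matrix(cons)
  coords <- fit$aligned[, , 1]
  slid <- girdlemorph:::slide_once(coords, tpl$config$curves, Bmat, cons)
  fx <- fixed_indices(tpl$config)
  expect_identical(slid[fx, ], coords[fx, ])
  expect_lte(bending_energy(Bmat, slid), bending_energy(Bmat, coords) + 1e-12)
})

test_that("sliding is a fixed point on identical configurations", {
  tpl <- the_template()
  copies <- replicate(3, tpl$config, simplify = FALSE)
  fit <- gpa(copies, slide = TRUE, max_iter = 5)
  # identical inputs: consensus equals each config; sliding moves nothing
  expect_lt(max(fit$procrustes_distances), 1e-8)
})

test_that("species means honor the rescaling contract", {
  set.seed(15)
  tpl <- the_template()
  a <- transformed_copy(tpl$config)
  # single-specimen species pass through centered
  m1 <- species_means(list(a), "sp1")
  expect_equal(m1$sp1$coords, sweep(a$coords, 2, colMeans(a$coords)))

  # rigid motions of one configuration: mean CS = mean of original CS
  b <- a; b$coords <- a$coords %*% t(girdlemorph:::random_rotation()) * 1.6 + 2
  mm <- species_means(list(a, b), c("sp", "sp"), slide = FALSE)
  expect_equal(centroid_size(mm$sp), mean(c(centroid_size(a), centroid_size(b))),
               tolerance = 1e-6)

  # idempotence: the mean of identical specimens is that specimen
  mi <- species_means(list(a, a, a), rep("s", 3), slide = FALSE)
  ac <- sweep(a$coords, 2, colMeans(a$coords))
  R <- girdlemorph:::procrustes_rotation(mi$s$coords, ac)
  expect_lt(max(abs(mi$s$coords %*% R - ac)), 1e-6)
})

test_that("landmark subsets partition the scheme and drop flagged species", {
  set.seed(16)
  tpl <- the_template()
  means <- lapply(1:6, function(i) transformed_copy(tpl$config, noise_sd = 0.02))
  names(means) <- sprintf("s%02d", 1:6)

  ds_i <- subset_landmarks(means, "fixed_only")
  expect_equal(dim(ds_i$fit$aligned)[1], 19)
  expect_length(ds_i$fit$curves, 0)

  bones <- c("scapula", "coracoid", "cleithrum", "clavicula")
  got <- integer(0)
  for (b in bones) {
    ds <- subset_landmarks(means, b, slide = FALSE)
    got <- c(got, which(tpl$config$bone == b))
  }
  expect_setequal(got, seq_len(nrow(tpl$config$coords)))

  ds_v <- subset_landmarks(means, "clavicula", exclude = c("s02", "s05"),
                           slide = FALSE)
  expect_length(ds_v$species, 4)
  expect_error(subset_landmarks(means, "femur"), "unknown bone")
})
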