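test_that("the 2-of-3 vote matches a per-voxel majority oracle", {
  set.seed(81)
  dims <- c(50, 50, 40)                 # 1e5 voxels
  a <- array(runif(prod(dims)) < 0.5, dims)
  b <- array(runif(prod(dims)) < 0.5, dims)
  cc <- array(runif(prod(dims)) < 0.5, dims)
  v <- vote_majority(a, b, cc)
  oracle <- array((a + b + cc) >= 2, dims)
  expect_identical(v, oracle)
  # voxel bone in exactly two stacks -> bone; in exactly one -> background
  expect_true(vote_majority(TRUE, TRUE, FALSE))
  expect_false(vote_majority(TRUE, FALSE, FALSE))
  # idempotence on identical stacks
  expect_identical(vote_majority(a, a, a), a)
})

test_that("Dice matches its closed forms", {
  m <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_equal(dice(m, m), 1)
  expect_equal(dice(m, !m), 0)
  a <- array(FALSE, c(4, 4, 1)); a[1:4] <- TRUE
  b <- array(FALSE, c(4, 4, 1)); b[1:8] <- TRUE
  expect_equal(dice(a, b), 2 / 3)        # A within B, |A| = |B|/2
  e <- array(FALSE, c(2, 2, 1))
  expect_equal(dice(e, e), 1)
  expect_error(dice(a, array(FALSE, c(2, 2, 1))), "shapes differ")
})

test_that("gray-window calibration implements the published formula", {
  # mean over bone-and-soft voxels of exactly 1000 -> center 556.188; the
  # volume includes darker background and a low bone tail so the window is
  # representable and non-degenerate
  vol <- array(300, c(10, 10, 10))
  vol[1:250] <- 800                                   # soft tissue
  vol[251:498] <- (300000 - 1040) / 248               # bone bulk
  vol[499:500] <- 520                                 # low bone tail
  bone <- array(FALSE, dim(vol)); bone[251:500] <- TRUE
  soft <- array(FALSE, dim(vol)); soft[1:250] <- TRUE
  expect_equal(mean(vol[bone | soft]), 1000, tolerance = 1e-9)
  cal <- calibrate_window(vol, bone, soft)
  expect_equal(cal$center, 556.188, tolerance = 1e-9)
  expect_equal(cal$window[1], 520, tolerance = 1e-6)  # lower limit = bone quantile
  expect_equal(cal$window[2], 2 * 556.188 - 520, tolerance = 1e-3)

  # degenerate window (center below the entire bone distribution) fails
  vol2 <- array(c(rep(800, 500), rep(1200, 500)), c(10, 10, 10))
  bone2 <- array(c(rep(FALSE, 500), rep(TRUE, 500)), c(10, 10, 10))
  expect_error(calibrate_window(vol2, bone2, !bone2), "calibration failure")
  expect_error(calibrate_window(vol, bone, bone), "disjoint")
})

test_that("windowing clips at most the allowed bone fraction to black", {
  ph <- make_ct_phantom(bone_gray = 3000, soft_gray = 500, noise_sd = 40,
                        radius_frac = 0.3, partial_volume = TRUE, seed = 2)
  rough <- dilate_mask(ph$mask, 1)
  cal <- calibrate_window(ph, rough, !rough)
  wr <- window_rescale(ph$volume * 1.0, cal)
  expect_lte(mean(wr[rough] == 0), 0.0015)
  expect_gt(cal$half_width, 0)
})

test_that("segmentation recovers the phantom and degrades with noise", {
  ph <- make_ct_phantom(seed = 3)
  seg <- segment_vote(ph)
  expect_gte(dice(seg$mask, ph$mask), 0.95)
  # idempotent on a noise-free phantom
  ph0 <- make_ct_phantom(noise_sd = 0, seed = 3)
  expect_equal(dice(segment_vote(ph0)$mask, ph0$mask), 1)
  # monotone (non-increasing) in noise, 3 replicates per level
  md <- vapply(c(5, 20, 40), function(ns) {
    mean(vapply(1:3, function(s) {
      p <- make_ct_phantom(noise_sd = ns, seed = s)
      dice(segment_vote(p)$mask, p$mask)
    }, 0))
  }, 0)
  expect_true(all(diff(md) <= 0.01))
})

test_that("segmentation is consistent under 90-degree rotation", {
  ph <- make_ct_phantom(dim = c(48, 48, 48), seed = 4)
  d0 <- dice(segment_vote(ph)$mask, ph$mask)
  rot <- aperm(ph$volume, c(2, 1, 3))
  seg_r <- segment_vote(rot)
  back <- aperm(seg_r$mask, c(2, 1, 3))
  d1 <- dice(back, ph$mask)
  expect_lt(abs(d0 - d1), 0.02)
})
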