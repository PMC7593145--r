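test_that("the anatomical frame satisfies its defining constraints", {
  assets <- the_assets()
  np <- assets$named_points
  fr <- build_frame(np)
  # template is already in canonical pose: identity rotation, zero origin
  expect_lt(max(abs(fr$R - diag(3))), 1e-9)
  expect_lt(max(abs(fr$origin)), 1e-9)
  expect_lt(max(fr$residuals), 1e-6)

  # rigid invariance: a rotated + translated girdle maps back to canon
  set.seed(71)
  R <- girdlemorph:::random_rotation()
  np2 <- np %*% t(R) + rep(1, nrow(np)) %o% c(3, -1, 2)
  rownames(np2) <- rownames(np)
  fr2 <- build_frame(np2)
  expect_lt(max(abs(fr2$to_frame(np2) - fr$to_frame(np))), 1e-9)
  # clavicula-coracoid line parallel to the x-z plane after transform
  line <- fr2$to_frame(np2["posteromedial_coracoid_tip", , drop = FALSE]) -
    fr2$to_frame(np2["anteromedial_clavicula_tip", , drop = FALSE])
  expect_lt(abs(line[2]), 1e-9)
})

test_that("the default muscle set matches the model definition", {
  assets <- the_assets()
  fr <- build_frame(assets$named_points)
  m3 <- build_default_muscles(fr, assets$named_points)
  expect_named(m3$muscles, c("anterior", "perpendicular", "posterior"))
  m5 <- build_default_muscles(fr, assets$named_points, has_sternum = TRUE,
                              has_episternum = TRUE)
  expect_length(m5$muscles, 5)
  # all muscles share one insertion point on the humerus
  ins <- unique(do.call(rbind, lapply(m5$muscles, `[[`, "insertion_local")))
  expect_identical(nrow(ins), 1L)
  # perpendicular muscle line has no anteroposterior component at reference
  pp <- girdlemorph:::muscle_path_points(m5$muscles$perpendicular)
  expect_lt(abs(pp[nrow(pp), 3] - pp[1, 3]), 1e-9)
  # requesting a muscle without its named point fails
  np_min <- assets$named_points[c("glenoid_center", "anteromedial_clavicula_tip",
                                  "posteromedial_coracoid_tip",
                                  "episternum_anterior_tip",
                                  "sternum_posterior_tip"), ]
  fr_min <- build_frame(np_min)
  expect_error(build_default_muscles(fr_min, np_min[-5, , drop = FALSE],
                                     has_sternum = TRUE), "required")
})

test_that("moment arms agree with the tendon-excursion derivative", {
  set.seed(72)
  worst <- 0
  for (i in 1:100) {
    m <- list(name = "rnd", origin = rnorm(3, sd = 3),
              via = if (runif(1) < 0.4) matrix(rnorm(3, sd = 2), 1, 3)
              else matrix(0, 0, 3),
              insertion_local = c(runif(1, 1, 4), 0, 0))
    tp <- runif(1, -1.2, 1.2); ta <- runif(1, -1.2, 1.2)
    for (ax in c("pr", "aa")) {
      r <- moment_arm(m, ax, tp, ta)
      rf <- girdlemorph:::moment_arm_fd(m, ax, tp, ta)
      worst <- max(worst, abs(r - rf))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("degenerate muscle geometries behave as specified", {
  through <- list(name = "t", origin = c(-3, 0, 0), via = matrix(0, 0, 3),
                  insertion_local = c(2, 0, 0))
  expect_equal(moment_arm(through, "pr"), 0)
  a <- 2; b <- 1.5
  closed_form <- list(name = "cf", origin = c(a, 0, -b), via = matrix(0, 0, 3),
                      insertion_local = c(a, 0, 0))
  expect_equal(moment_arm(closed_form, "pr"), a, tolerance = 1e-12)
  zero_seg <- list(name = "z", origin = c(2, 0, 0), via = matrix(0, 0, 3),
                   insertion_local = c(2, 0, 0))
  expect_error(moment_arm(zero_seg, "pr"), "zero-length")
})

test_that("moment arms are invariant under rigid motion of the whole model", {
  assets <- the_assets()
  np <- assets$named_points
  set.seed(73)
  R <- girdlemorph:::random_rotation()
  np2 <- np %*% t(R) + rep(1, nrow(np)) %o% rnorm(3, sd = 4)
  rownames(np2) <- rownames(np)
  m1 <- build_default_muscles(build_frame(np), np)
  m2 <- build_default_muscles(build_frame(np2), np2)
  for (nm in names(m1$muscles))
    for (th in c(-0.5, 0, 0.7))
      expect_equal(moment_arm(m1$muscles[[nm]], "pr", theta_pr = th),
                   moment_arm(m2$muscles[[nm]], "pr", theta_pr = th),
                   tolerance = 1e-9)
})

test_that("sweeps derive zero crossings, symmetry, and grid consistency", {
  # symmetric geometry: origin at insertion's z-level in the sagittal-ish
  # plane -> zero crossing exactly at the reference position
  sym <- list(name = "sym", origin = c(-4, -1, 0), via = matrix(0, 0, 3),
              insertion_local = c(2, 0, 0))
  model <- structure(list(muscles = list(sym = sym), frame = NULL,
                          humerus_length = 5, insertion_frac = 0.4),
                     class = "muscle_model")
  sw <- sweep_moment_arms(model, axis_of = c(sym = "pr"))
  expect_equal(moment_arm(sym, "pr", theta_pr = 0), 0, tolerance = 1e-12)
  expect_true(any(abs(sw$zero_crossings$sym) < 1e-9))

  # halving the step leaves shared grid points identical
  sw2 <- sweep_moment_arms(model, axis_of = c(sym = "pr"), step = 2.5)
  shared <- sw$curves$angle_deg
  sub <- sw2$curves[match(shared, sw2$curves$angle_deg), "moment_arm_mm"]
  expect_identical(sub, sw$curves$moment_arm_mm)
})

test_that("a posteriorly displaced coracoid tip enlarges the retractor lever", {
  base <- girdle_template()
  disp <- girdle_template(coracoid_angle = 35)
  get_model <- function(tpl) {
    assets <- make_girdle_assets(tpl)
    build_default_muscles(build_frame(assets$named_points), assets$named_points)
  }
  mb <- get_model(base); md <- get_model(disp)
  expect_gt(moment_arm(md$muscles$posterior, "pr"),
            moment_arm(mb$muscles$posterior, "pr"))
  sb <- sweep_moment_arms(mb); sd_ <- sweep_moment_arms(md)
  expect_gt(sd_$action_ranges$posterior$positive_width,
            sb$action_ranges$posterior$positive_width)
})

test_that("muscle paths crossing bone are detected and reported", {
  assets <- the_assets()
  # a segment deliberately running through the scapula blade
  thru <- list(name = "x", origin = c(0.8, 8, 3), via = matrix(0, 0, 3),
               insertion_local = c(0.8, 8, -3))
  expect_gt(check_path_intersections(thru, assets$meshes["scapula"]), 0)
  clear <- list(name = "c", origin = c(20, 20, 0), via = matrix(0, 0, 3),
                insertion_local = c(25, 20, 0))
  expect_identical(check_path_intersections(clear, assets$meshes), 0L)
})
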