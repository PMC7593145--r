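test_that("simulated trees are ultrametric, binary, unit height, seeded", {
  tr2 <- sim_tree(2, seed = 1)
  depths <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(depths, c(1, 1))

  tr <- sim_tree(64, seed = 1)
  expect_length(tr$tip.label, 64)
  expect_identical(tr$Nnode, 63L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)

  expect_identical(ape::write.tree(sim_tree(16, seed = 9)),
                   ape::write.tree(sim_tree(16, seed = 9)))
  expect_error(sim_tree(1), "at least 2")
})

test_that("all variance sources off reproduces the template exactly", {
  tpl <- the_template()
  tree <- sim_tree(8, seed = 2)
  cfg <- synth_config(n_species = 8, bm_rate = 0, group_effect = 0,
                      allometry_slope = 0, noise_sd = 0, size_sd = 0, seed = 3)
  smp <- sim_species_shapes(tree, tpl, cfg)
  for (sp in smp$specimens)
    expect_equal(sp$coords, tpl$config$coords, tolerance = 1e-12)
})

test_that("group_map must cover every tip; invariants hold on cfg", {
  tpl <- the_template()
  tree <- sim_tree(8, seed = 2)
  bad_map <- stats::setNames(rep("swimming", 7), tree$tip.label[1:7])
  expect_error(sim_species_shapes(tree, tpl, synth_config(n_species = 8),
                                  group_map = bad_map), "tip labels")
  expect_error(synth_config(n_species = 4), "at least 8")
  expect_error(synth_config(bm_rate = -1), "non-negative")
})

test_that("identical seeds give bit-identical synthetic samples", {
  tpl <- the_template()
  tree <- sim_tree(8, seed = 4)
  cfg <- synth_config(n_species = 8, seed = 7)
  a <- sim_species_shapes(tree, tpl, cfg)
  b <- sim_species_shapes(tree, tpl, cfg)
  expect_identical(lapply(a$specimens, `[[`, "coords"),
                   lapply(b$specimens, `[[`, "coords"))
  expect_identical(a$logCS, b$logCS)
})

test_that("doubling the Brownian rate doubles expected squared displacement", {
  tpl <- the_template()
  tree <- sim_tree(10, seed = 5)
  msd <- function(rate, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- synth_config(n_species = 10, bm_rate = rate, group_effect = 0,
                          allometry_slope = 0, noise_sd = 0, size_sd = 0,
                          seed = s)
      smp <- sim_species_shapes(tree, tpl, cfg)
      mean(rowSums(smp$truth$bm^2))
    }, 0))
  }
  r1 <- msd(0.01, 1:100)
  r2 <- msd(0.02, 101:200)
  expect_lt(abs(r2 / r1 - 2), 0.2)   # ratio 2 within 10%
})

test_that("structured tet beams partition the box exactly", {
  beam <- make_tet_beam(10, 1, 1, c(10, 2, 2))
  vols <- tet_volumes(beam$nodes, beam$elems)
  expect_true(all(vols > 0))
  expect_equal(sum(vols), 10)
  areas <- face_areas(beam$nodes, beam$face_sets$end_max)
  expect_equal(sum(areas), 1)
  # sheared (curved) beam keeps its volume and face area
  bent <- make_tet_beam(10, 1, 1, c(10, 2, 2), curvature = 0.1)
  expect_equal(sum(tet_volumes(bent$nodes, bent$elems)), 10)
  expect_true(all(tet_volumes(bent$nodes, bent$elems) > 0))
  expect_error(make_tet_beam(0, 1, 1), "positive")
})

test_that("girdle surfaces are closed and carry their named points", {
  assets <- the_assets()
  expect_named(assets$meshes, c("scapula", "coracoid", "cleithrum", "clavicula"))
  for (m in assets$meshes) {
    expect_identical(euler_characteristic(m), 2L)
    expect_gt(mesh_volume(m), 0)
  }
  np <- assets$named_points
  verts <- do.call(rbind, lapply(assets$meshes, `[[`, "vertices"))
  for (nm in c("glenoid_center", "anteromedial_clavicula_tip",
               "posteromedial_coracoid_tip", "coracoid_anteromedial_tip")) {
    d <- min(sqrt(rowSums(sweep(verts, 2, np[nm, ])^2)))
    expect_lt(d, 1e-6)
  }
  lo <- apply(verts, 2, min); hi <- apply(verts, 2, max)
  for (i in seq_len(nrow(np)))
    expect_true(all(np[i, ] >= lo & np[i, ] <= hi))
})

test_that("doubling the coracoid length shifts its medial tip along the axis", {
  t1 <- girdle_template(coracoid_length = 7)
  t2 <- girdle_template(coracoid_length = 14)
  shift <- t2$named_points["posteromedial_coracoid_tip", ] -
    t1$named_points["posteromedial_coracoid_tip", ]
  expect_equal(sqrt(sum(shift^2)), 7, tolerance = 1e-9)
  expect_equal(drop(shift %*% t1$internals$axis_c), 7, tolerance = 1e-9)
})

test_that("CT phantoms honor their gray-value contract", {
  ph0 <- make_ct_phantom(noise_sd = 0, seed = 1)
  expect_identical(sort(unique(as.vector(ph0$volume))), c(100L, 200L))
  # law of total expectation at zero noise
  f <- mean(ph0$mask)
  expect_equal(mean(ph0$volume), f * 200 + (1 - f) * 100, tolerance = 1e-9)

  a <- make_ct_phantom(seed = 5); b <- make_ct_phantom(seed = 5)
  expect_identical(a$volume, b$volume)
  expect_error(make_ct_phantom(bone_gray = 90, soft_gray = 100), "exceed")
})
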