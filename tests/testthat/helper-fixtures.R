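# Shared fixtures, built in code. The default template is moderately large
# (244 landmarks), so it is constructed once per test run.

the_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- girdle_template()
    tpl
  }
})

the_assets <- local({
  a <- NULL
  function() {
    if (is.null(a)) a <<- make_girdle_assets(the_template())
    a
  }
})

# A similarity-transformed (+ optionally noisy) copy of a configuration.
transformed_copy <- function(config, noise_sd = 0, scale = NULL) {
  R <- girdlemorph:::random_rotation()
  s <- scale %||% stats::runif(1, 0.5, 2)
  out <- config
  out$coords <- config$coords %*% t(R) * s +
    rep(1, nrow(config$coords)) %o% stats::rnorm(3, sd = 5)
  if (noise_sd > 0)
    out$coords <- out$coords + matrix(stats::rnorm(length(out$coords), 0, noise_sd),
                                      ncol = 3)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small 3D configuration for TPS tests: random but well-conditioned.
random_points <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(3 * k), k, 3)
}

# Species-mean-level synthetic dataset on the fixed-landmark subset; the
# statistical simulation workhorse (sliding plays no role for dataset i).
simulate_fixed_dataset <- function(n_species = 24, seed = 1, group_effect = 0,
                                   bm_rate = 0.01, noise_sd = 0.05,
                                   specimens = 1) {
  tpl <- the_template()
  tree <- sim_tree(n_species, seed = seed)
  cfg <- synth_config(n_species = n_species, specimens_per_species = specimens,
                      bm_rate = bm_rate, group_effect = group_effect,
                      noise_sd = noise_sd, seed = seed + 1000L)
  smp <- sim_species_shapes(tree, tpl, cfg)
  means <- species_means(smp$specimens, smp$specimen_species, slide = FALSE)
  ds <- subset_landmarks(means, "fixed_only")
  list(Y = shape_matrix(ds$fit, names = ds$species), logCS = ds$logCS,
       group = smp$group, tree = tree, sample = smp)
}
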