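# Synthetic-data generators: the study conditions with known ground truth.

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Pure-birth (Yule) tree with the total height rescaled to 1 and tip labels
#' `s001, s002, ...`. Identical `(n_tips, seed)` pairs yield bit-identical
#' trees.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer RNG seed.
#' @return an `ape::phylo` tree.
#' @export
sim_tree <- function(n_tips, seed = 1) {
  stop_if(n_tips < 2, "n_tips must be at least 2")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("s%03d", seq_len(n_tips))
  tr
}

#' Synthetic-sample configuration
#'
#' Bundles the generator settings for [sim_species_shapes()]. The defaults
#' are the package's reference study conditions: 64 species in six locomotor
#' groups, mostly one specimen per species, Brownian-motion shape evolution
#' with additive locomotor-group effects and size allometry, and small
#' within-species digitizing noise.
#'
#' @param n_species number of species (>= 8).
#' @param specimens_per_species specimens digitized per species.
#' @param group_labels the six locomotor-group labels.
#' @param bm_rate Brownian-motion rate: coordinate variance (mm^2) per unit
#'   branch length, isotropic and independent over all 3k coordinates.
#' @param group_effect magnitude (mm) of the fixed per-group displacement
#'   along a random unit direction in coordinate space.
#' @param allometry_slope shape displacement (mm) per unit log centroid size
#'   along a fixed random unit direction.
#' @param noise_sd within-species landmark noise SD (mm).
#' @param size_sd SD of species log size factors.
#' @param n_clav_absent number of species flagged clavicula-absent (their
#'   clavicula landmarks are masked missing, exercising the
#'   missing-landmark path).
#' @param seed integer RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_species = 64, specimens_per_species = 1,
                         group_labels = c("swimming", "walking_hopping",
                                          "jumping", "backward_burrowing",
                                          "headfirst_burrowing", "climbing"),
                         bm_rate = 0.01, group_effect = 0.5,
                         allometry_slope = 0.5, noise_sd = 0.05,
                         size_sd = 0.3, n_clav_absent = 0, seed = 1) {
  stop_if(n_species < 8, "n_species must be at least 8")
  stop_if(any(c(bm_rate, group_effect, allometry_slope, noise_sd, size_sd) < 0),
          "variances and effect magnitudes must be non-negative")
  stop_if(length(group_labels) != 6, "six locomotor groups are expected")
  structure(list(n_species = n_species,
                 specimens_per_species = specimens_per_species,
                 group_labels = group_labels, bm_rate = bm_rate,
                 group_effect = group_effect,
                 allometry_slope = allometry_slope, noise_sd = noise_sd,
                 size_sd = size_sd, n_clav_absent = n_clav_absent,
                 seed = seed),
            class = "synth_config")
}

# Brownian deviations accumulated root -> tip; one column per coordinate.
sim_bm_tips <- function(tree, rate, p) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(0, n_node, p)
  for (ei in rev(ape::postorder(tree))) {   # parents before children
    par <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    states[ch, ] <- states[par, ] +
      stats::rnorm(p, 0, sqrt(rate * tree$edge.length[ei]))
  }
  states[seq_len(n_tip), , drop = FALSE]
}

#' Simulate specimen landmark configurations on a phylogeny
#'
#' Species mean shapes evolve by isotropic multivariate Brownian motion on
#' the tree, plus a fixed unit-direction displacement per locomotor group
#' (magnitude `group_effect`), plus allometric displacement proportional to
#' centered log size along a second fixed unit direction. Each species is
#' scaled by a lognormal size factor; specimens are the species mean plus
#' iid Gaussian landmark noise. All ground-truth components are returned for
#' recovery tests.
#'
#' @param tree `ape::phylo`; tip labels name the species.
#' @param template a `girdle_template`.
#' @param cfg a [synth_config()].
#' @param group_map named character vector species -> group; defaults to a
#'   balanced random assignment.
#' @return a `synth_sample`: `specimens` (list of `landmark_config`),
#'   `specimen_species`, `species`, `group` (factor), `logCS` (species log
#'   centroid sizes), `clav_absent` (species lacking a clavicula), `truth`
#'   (species mean coordinates, group/allometry directions, BM deviations),
#'   and the inputs.
#' @export
sim_species_shapes <- function(tree, template, cfg = synth_config(),
                               group_map = NULL) {
  set.seed(cfg$seed)
  species <- tree$tip.label
  n <- length(species)
  if (is.null(group_map)) {
    group_map <- stats::setNames(
      sample(rep_len(cfg$group_labels, n)), species)
  }
  stop_if(!setequal(names(group_map), species),
          "group_map must have exactly the tree's tip labels as names")
  group <- factor(group_map[species], levels = cfg$group_labels)

  base <- template$config
  k <- nrow(base$coords); p <- 3 * k
  tvec <- as.vector(t(base$coords))

  u_group <- vapply(cfg$group_labels, function(g)
    unit_vec(stats::rnorm(p)), numeric(p))
  u_allom <- unit_vec(stats::rnorm(p))
  direction_cos <- drop(crossprod(u_allom, u_group))  # reported, not enforced

  log_size <- stats::rnorm(n, 0, cfg$size_sd)
  log_size <- log_size - mean(log_size)
  bm <- if (cfg$bm_rate > 0) sim_bm_tips(tree, cfg$bm_rate, p) else
    matrix(0, n, p)

  mean_vec <- matrix(NA_real_, n, p, dimnames = list(species, NULL))
  for (i in seq_len(n)) {
    mean_vec[i, ] <- tvec + bm[i, ] +
      cfg$group_effect * u_group[, as.character(group[i])] +
      cfg$allometry_slope * log_size[i] * u_allom
  }

  clav_absent <- character(0)
  clav_mask <- base$bone == "clavicula"
  if (cfg$n_clav_absent > 0)
    clav_absent <- sort(sample(species, cfg$n_clav_absent))

  specimens <- list(); specimen_species <- character(0)
  logCS <- stats::setNames(numeric(n), species)
  for (i in seq_len(n)) {
    m <- matrix(mean_vec[i, ], k, 3, byrow = TRUE) * exp(log_size[i])
    logCS[i] <- log(centroid_size(m))
    for (r in seq_len(cfg$specimens_per_species)) {
      coords <- m + matrix(stats::rnorm(p, 0, cfg$noise_sd), k, 3)
      dimnames(coords) <- dimnames(base$coords)
      cc <- landmark_config(coords, curves = base$curves, bone = base$bone,
                            side = base$side,
                            missing = if (species[i] %in% clav_absent)
                              clav_mask else rep(FALSE, k))
      specimens[[length(specimens) + 1]] <- cc
      specimen_species <- c(specimen_species, species[i])
    }
  }

  structure(list(specimens = specimens, specimen_species = specimen_species,
                 species = species, group = group, logCS = logCS,
                 clav_absent = clav_absent,
                 truth = list(mean_vec = mean_vec, u_group = u_group,
                              u_allom = u_allom, bm = bm,
                              log_size = log_size,
                              group_allometry_cos = direction_cos),
                 tree = tree, template = template, cfg = cfg),
            class = "synth_sample")
}

#' @export
print.synth_sample <- function(x, ...) {
  cat(sprintf("synth_sample: %d specimens of %d species in %d groups\n",
              length(x$specimens), length(x$species), nlevels(x$group)))
  invisible(x)
}
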