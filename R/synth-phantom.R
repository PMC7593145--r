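# Two-tissue CT phantoms with ground-truth masks.

#' Generate a two-tissue CT phantom
#'
#' Builds a 16-bit gray volume in which voxels inside a bone-like shape are
#' drawn from N(bone_gray, noise_sd) and the remainder (soft tissue) from
#' N(soft_gray, noise_sd), clipped to the representable range [0, 65535] and
#' rounded to integers. The ground-truth bone mask is returned alongside.
#'
#' @param dim integer vector of volume dimensions (voxels), e.g.
#'   `c(64, 64, 64)`.
#' @param shape `"rod"` (a bent cylindrical rod, the default girdle-bone
#'   stand-in) or `"ball"`.
#' @param bone_gray,soft_gray class mean gray values; `bone_gray` must
#'   exceed `soft_gray`.
#' @param noise_sd gray-value noise SD (0 gives exactly two gray values).
#' @param voxel_size voxel edge length (mm).
#' @param radius_frac shape radius as a fraction of the smallest dimension.
#' @param partial_volume emulate partial-volume voxels: grays at the shape
#'   boundary blend linearly between the class means over ~1 voxel, giving
#'   the bone gray distribution the low tail real micro-CT has. `FALSE`
#'   (default) yields exactly two class means before noise.
#' @param seed integer RNG seed; identical seeds give identical volumes.
#' @return a `ct_phantom`: list with `volume` (integer array), `mask`
#'   (logical truth array), `voxel_size`, and the generator settings.
#' @export
make_ct_phantom <- function(dim = c(64, 64, 64), shape = c("rod", "ball"),
                            bone_gray = 200, soft_gray = 100, noise_sd = 15,
                            voxel_size = 0.01, radius_frac = 0.14,
                            partial_volume = FALSE, seed = 1) {
  shape <- match.arg(shape)
  stop_if(bone_gray <= soft_gray, "bone_gray must exceed soft_gray")
  dim <- as.integer(dim)
  stop_if(length(dim) != 3 || any(dim < 4), "dim must be three integers >= 4")
  set.seed(seed)

  idx <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                     z = seq_len(dim[3]), KEEP.OUT.ATTRS = FALSE)
  ctr <- (dim + 1) / 2
  r <- radius_frac * min(dim)
  if (shape == "ball") {
    d2 <- (idx$x - ctr[1])^2 + (idx$y - ctr[2])^2 + (idx$z - ctr[3])^2
    sd_surf <- sqrt(d2) - 2 * r          # signed distance to surface
  } else {
    # rod along x, bowed in y: axis y = ctr + bow * sin(pi * t)
    t <- (idx$x - 1) / (dim[1] - 1)
    ay <- ctr[2] + 0.18 * dim[2] * sin(pi * t)
    d2 <- (idx$y - ay)^2 + (idx$z - ctr[3])^2
    sd_surf <- sqrt(d2) - r
    sd_surf[t < 0.1 | t > 0.9] <- pmax(sd_surf[t < 0.1 | t > 0.9], 0.5)
  }
  mask <- array(sd_surf <= 0, dim)

  if (partial_volume) {
    coverage <- pmin(pmax(0.5 - sd_surf, 0), 1)     # linear blend over 1 voxel
    vol <- array(soft_gray + (bone_gray - soft_gray) * coverage, dim)
  } else {
    vol <- array(ifelse(mask, bone_gray, soft_gray), dim)
  }
  if (noise_sd > 0) vol <- vol + array(stats::rnorm(prod(dim), 0, noise_sd), dim)
  vol <- array(as.integer(round(pmin(pmax(vol, 0), 65535))), dim)

  structure(list(volume = vol, mask = mask, voxel_size = voxel_size,
                 bone_gray = bone_gray, soft_gray = soft_gray,
                 noise_sd = noise_sd, shape = shape, seed = seed),
            class = "ct_phantom")
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("ct_phantom: %s, %s voxels, bone %g / soft %g (noise SD %g)\n",
              x$shape, paste(dim(x$volume), collapse = "x"),
              x$bone_gray, x$soft_gray, x$noise_sd))
  invisible(x)
}
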