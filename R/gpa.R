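# Generalized Procrustes Analysis with bending-energy sliding semilandmarks.
#
# Partial Procrustes superimposition: configurations are centered, scaled to
# unit centroid size, and rotated (SVD orthogonal Procrustes, reflections
# disallowed) onto an iteratively updated consensus. When sliding is enabled,
# each iteration relaxes curve semilandmarks along tangent lines so that the
# thin-plate-spline bending energy against the current consensus is
# minimized, then projects the slid points back onto the original piecewise
# linear curve. One sliding pass per GPA iteration.

center_scale <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  cs <- sqrt(sum(x^2))
  stop_if(cs <= 0, "degenerate configuration: all landmarks coincide")
  x / cs
}

# Rotation (det +1) that best maps x onto y, both centered.
procrustes_rotation <- function(x, y) {
  s <- svd(t(x) %*% y)
  d <- sign(det(s$u %*% t(s$v)))
  u <- s$u; u[, 3] <- u[, 3] * d
  u %*% t(s$v)
}

#' Procrustes distance between two aligned configurations
#' @param a,b k x 3 coordinate matrices (already superimposed).
#' @return square root of the summed squared coordinate differences.
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

# Tangent directions for the semilandmarks of one configuration.
# Central differences of curve neighbors; one-sided at interior points
# adjacent to fixed curve endpoints.
semilandmark_tangents <- function(coords, curves) {
  semis <- integer(0); tang <- NULL
  for (idx in curves) {
    n <- length(idx)
    for (j in 2:(n - 1)) {
      i <- idx[j]
      t_vec <- if (j == 2) coords[idx[j + 1], ] - coords[i, ]
      else if (j == n - 1) coords[i, ] - coords[idx[j - 1], ]
      else coords[idx[j + 1], ] - coords[idx[j - 1], ]
      if (sqrt(sum(t_vec^2)) < 1e-7)    # collapsed neighbors: use the chord
        t_vec <- coords[idx[n], ] - coords[idx[1], ]
      semis <- c(semis, i)
      tang <- rbind(tang, unit_vec(t_vec))
    }
  }
  list(idx = semis, tangents = tang)
}

# Closest points on a polyline for a whole set of points (vectorized over
# the points; loop over polyline segments).
project_onto_polyline <- function(P, poly) {
  P <- rbind(P)
  best <- matrix(poly[1, ], nrow(P), 3, byrow = TRUE)
  bd <- rowSums(sweep(P, 2, poly[1, ])^2)
  for (s in seq_len(nrow(poly) - 1)) {
    a <- poly[s, ]; ab <- poly[s + 1, ] - a
    len2 <- sum(ab^2)
    t <- if (len2 < 1e-24) rep(0, nrow(P)) else
      pmin(pmax(sweep(P, 2, a) %*% ab / len2, 0), 1)
    Q <- sweep(drop(t) %o% ab, 2, a, `+`)
    d <- rowSums((P - Q)^2)
    upd <- d < bd
    if (any(upd)) { best[upd, ] <- Q[upd, , drop = FALSE]; bd[upd] <- d[upd] }
  }
  best
}

# One bending-energy sliding pass of `coords` against `consensus`.
# Returns the updated coordinates; guaranteed not to increase the bending
# energy versus the consensus (step is halved, and finally abandoned, if the
# polyline re-projection would increase it).
slide_once <- function(coords, curves, Bmat, consensus) {
  tg <- semilandmark_tangents(coords, curves)
  s <- tg$idx; Tm <- tg$tangents
  # minimize sum_d (y_d + T_d)' B (y_d + T_d) over tangent amplitudes tau
  A <- matrix(0, length(s), length(s))
  b <- numeric(length(s))
  By <- Bmat %*% coords            # k x 3
  for (d in 1:3) {
    A <- A + (Tm[, d] %o% Tm[, d]) * Bmat[s, s, drop = FALSE]
    b <- b + Tm[, d] * By[s, d]
  }
  diag(A) <- diag(A) + 1e-12 * max(abs(diag(A)), 1)
  tau <- tryCatch(drop(solve(A, -b)), error = function(e) rep(0, length(s)))

  be0 <- bending_energy(Bmat, coords)
  step <- 1
  for (try in 1:6) {
    new <- coords
    new[s, ] <- coords[s, ] + step * tau * Tm
    # re-project onto the pre-slide piecewise-linear curves
    for (idx in curves) {
      inner <- idx[-c(1, length(idx))]
      new[inner, ] <- project_onto_polyline(new[inner, , drop = FALSE],
                                            coords[idx, , drop = FALSE])
    }
    if (bending_energy(Bmat, new) <= be0 + 1e-12) return(new)
    step <- step / 2
  }
  coords
}

#' Generalized Procrustes Analysis
#'
#' Superimposes a set of landmark configurations by partial Procrustes
#' analysis (centering, scaling to unit centroid size, SVD rotation with
#' reflections disallowed) onto an iteratively updated consensus, optionally
#' sliding curve semilandmarks to minimize thin-plate-spline bending energy
#' against the consensus.
#'
#' @param configs list of `landmark_config` objects (complete, identical
#'   landmark schemes) or a k x 3 x n array.
#' @param slide logical; slide semilandmarks along their curve tangents?
#'   Ignored when the scheme has no curves.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iter maximum number of GPA iterations; non-convergence is
#'   flagged in the result, not an error.
#' @return a `gpa_fit` object: aligned coordinate array `aligned`
#'   (k x 3 x n, centered, unit centroid size), `consensus`, original
#'   `centroid_sizes`, per-configuration Procrustes distances to the
#'   consensus, iteration count, convergence flag, and (when sliding) the
#'   per-pass bending-energy trace.
#' @export
gpa <- function(configs, slide = TRUE, tol = 1e-6, max_iter = 20) {
  if (is.array(configs) && length(dim(configs)) == 3) {
    arr <- configs; curves <- list()
    scheme <- NULL
  } else {
    stop_if(length(configs) < 1, "need at least one configuration")
    scheme <- configs[[1]]
    k0 <- nrow(scheme$coords)
    stop_if(any(vapply(configs, function(cc) nrow(cc$coords), 0L) != k0),
            "all configurations must share one landmark scheme")
    stop_if(any(vapply(configs, function(cc) any(cc$missing), TRUE)),
            "estimate missing landmarks before GPA")
    arr <- simplify2array(lapply(configs, function(cc) cc$coords))
    curves <- scheme$curves
  }
  k <- dim(arr)[1]; n <- dim(arr)[3]
  do_slide <- slide && length(curves) > 0 && n >= 2

  cs <- apply(arr, 3, centroid_size)
  aligned <- arr
  for (i in seq_len(n)) aligned[, , i] <- center_scale(arr[, , i])

  consensus <- aligned[, , 1]
  converged <- FALSE; iter <- 0L; be_trace <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      R <- procrustes_rotation(aligned[, , i], consensus)
      aligned[, , i] <- aligned[, , i] %*% R
    }
    if (do_slide) {
      Bmat <- tps_bending_matrix(consensus)
      be_pass <- 0
      for (i in seq_len(n)) {
        aligned[, , i] <- slide_once(aligned[, , i], curves, Bmat, consensus)
        aligned[, , i] <- center_scale(aligned[, , i])
        R <- procrustes_rotation(aligned[, , i], consensus)
        aligned[, , i] <- aligned[, , i] %*% R
        be_pass <- be_pass + bending_energy(Bmat, aligned[, , i])
      }
      be_trace <- c(be_trace, be_pass)
    }
    new_cons <- center_scale(apply(aligned, c(1, 2), mean))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  # final rotation pass so every configuration is optimally aligned, then
  # refresh the consensus so it is exactly the coordinate-wise mean
  for (i in seq_len(n)) {
    R <- procrustes_rotation(aligned[, , i], consensus)
    aligned[, , i] <- aligned[, , i] %*% R
  }
  consensus <- center_scale(apply(aligned, c(1, 2), mean))

  pd <- apply(aligned, 3, procrustes_distance, b = consensus)
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = cs, procrustes_distances = pd,
                 n_iterations = iter, converged = converged,
                 bending_energy_trace = be_trace,
                 curves = curves, scheme = scheme),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("gpa_fit: %d configurations, %d landmarks, %d iterations (%s)\n",
              dim(x$aligned)[3], dim(x$aligned)[1], x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  mean Procrustes distance to consensus: %.3g\n",
              mean(x$procrustes_distances)))
  invisible(x)
}

#' Two-level species mean shapes
#'
#' For each species: its specimens are superimposed by [gpa()] (with
#' semilandmark sliding when the scheme has curves), each aligned specimen is
#' rescaled to its own original centroid size, and the coordinate-wise mean
#' is taken. Species represented by a single specimen pass through unchanged
#' apart from centering. The resulting species mean configurations retain
#' size, so log centroid size can be taken downstream.
#'
#' @param configs list of complete `landmark_config` objects.
#' @param species character/factor of length `length(configs)`.
#' @param slide,tol,max_iter passed to [gpa()].
#' @return named list of species mean `landmark_config`s (names = species,
#'   ordered by first appearance).
#' @export
species_means <- function(configs, species, slide = TRUE, tol = 1e-6,
                          max_iter = 20) {
  species <- as.character(species)
  stop_if(length(species) != length(configs),
          "species must label every configuration")
  out <- list()
  for (sp in unique(species)) {
    sel <- which(species == sp)
    scheme <- configs[[sel[1]]]
    if (length(sel) == 1) {
      m <- scheme
      m$coords <- sweep(m$coords, 2, colMeans(m$coords))
    } else {
      fit <- gpa(configs[sel], slide = slide, tol = tol, max_iter = max_iter)
      rescaled <- fit$aligned
      for (i in seq_along(sel))
        rescaled[, , i] <- rescaled[, , i] * fit$centroid_sizes[i]
      m <- scheme
      m$coords <- apply(rescaled, c(1, 2), mean)
      dimnames(m$coords) <- dimnames(scheme$coords)
    }
    out[[sp]] <- m
  }
  out
}

#' Extract landmark subsets (datasets i-v) and re-superimpose
#'
#' Builds the analysis datasets from species mean configurations:
#' dataset i keeps only the fixed landmarks (curve endpoints included,
#' curves dropped); datasets ii-v keep all landmarks and semilandmarks of a
#' single bone. Species flagged as lacking the clavicula are excluded from
#' the clavicula subset. The subset is then re-superimposed by [gpa()]
#' (with sliding whenever curves remain).
#'
#' @param means named list of species mean `landmark_config`s.
#' @param selector `"fixed_only"` or a bone name
#'   (`"scapula"`, `"coracoid"`, `"cleithrum"`, `"clavicula"`).
#' @param exclude character vector of species to drop (used for
#'   clavicula-less species on the clavicula subset).
#' @param slide,tol,max_iter passed to [gpa()].
#' @return list with the subset `gpa_fit` (`fit`), the retained `species`,
#'   log centroid sizes of the subset configurations (`logCS`), and the
#'   subset scheme.
#' @export
subset_landmarks <- function(means, selector, exclude = character(0),
                             slide = TRUE, tol = 1e-6, max_iter = 20) {
  stop_if(length(means) == 0, "empty dataset")
  scheme <- means[[1]]
  if (identical(selector, "fixed_only")) {
    keep <- fixed_indices(scheme)
    new_curves <- list()
  } else {
    stop_if(!selector %in% scheme$bone,
            "unknown bone selector '", selector, "'")
    keep <- which(scheme$bone == selector)
    new_curves <- lapply(scheme$curves, function(idx)
      if (all(idx %in% keep)) match(idx, keep) else NULL)
    new_curves <- Filter(Negate(is.null), new_curves)
  }
  stop_if(length(keep) == 0, "empty landmark subset")
  species <- setdiff(names(means), exclude)
  stop_if(length(species) < 2, "fewer than two species retained in subset")
  subs <- lapply(means[species], function(m)
    landmark_config(m$coords[keep, , drop = FALSE], curves = new_curves,
                    bone = m$bone[keep], side = m$side))
  cs <- vapply(subs, centroid_size, 0)
  fit <- gpa(subs, slide = slide && length(new_curves) > 0,
             tol = tol, max_iter = max_iter)
  list(fit = fit, species = species, logCS = log(cs), scheme = subs[[1]],
       selector = selector)
}

#' Flatten an aligned sample into a species-by-coordinates matrix
#' @param fit a `gpa_fit`.
#' @param names optional row names (e.g. species).
#' @return n x 3k matrix, columns ordered landmark-major (x1,y1,z1,x2,...).
#' @export
shape_matrix <- function(fit, names = NULL) {
  arr <- fit$aligned
  Y <- t(apply(arr, 3, function(m) as.vector(t(m))))
  if (!is.null(names)) rownames(Y) <- names
  Y
}
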