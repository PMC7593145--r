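# Thin-plate splines in three dimensions.
#
# Kernel U(r) = r (the 3D biharmonic radial basis). With this kernel the
# upper-left k x k block of the inverse TPS system matrix is negative
# semidefinite on the non-affine subspace, so the bending energy is the
# NEGATED quadratic form; `tps_bending_matrix` returns the positive
# semidefinite version and all bending energies reported by this package
# are >= 0, with exactly 0 for affine deformations.

tps_kernel <- function(d) d

tps_system <- function(ref) {
  k <- nrow(ref)
  K <- tps_kernel(as.matrix(stats::dist(ref)))
  Q <- cbind(1, ref)
  rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4, 4)))
}

#' Fit a 3D thin-plate-spline warp between two point sets
#'
#' Solves the TPS interpolation system mapping `ref` exactly onto `target`.
#' At least 5 non-coplanar reference points are required; coplanar or
#' duplicated points make the system singular and raise an error.
#'
#' @param ref k x 3 matrix of reference points.
#' @param target k x 3 matrix of corresponding target points.
#' @return a `tps_warp` object: a function-bearing list with components
#'   `warp(pts)` (maps arbitrary points through the spline), `bending_energy`
#'   (non-negative scalar, 0 for affine maps) and the spline coefficients.
#' @export
tps_fit <- function(ref, target) {
  ref <- as.matrix(ref); target <- as.matrix(target)
  stop_if(nrow(ref) != nrow(target), "ref and target must have equal point counts")
  stop_if(nrow(ref) < 5, "at least 5 correspondence points are required in 3D")
  k <- nrow(ref)
  L <- tps_system(ref)
  rhs <- rbind(target, matrix(0, 4, 3))
  coefs <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system (coplanar or duplicated points?): ",
         conditionMessage(e), call. = FALSE))
  W <- coefs[seq_len(k), , drop = FALSE]
  A <- coefs[k + 1:4, , drop = FALSE]
  # bending energy = -tr(W' K W) with this kernel sign (>= 0, see header)
  K <- tps_kernel(as.matrix(stats::dist(ref)))
  be <- -sum(diag(t(W) %*% K %*% W))

  warp <- function(pts) {
    pts <- rbind(as.matrix(pts))
    U <- tps_kernel(outer(seq_len(nrow(pts)), seq_len(k), function(i, j)
      sqrt(rowSums((pts[i, , drop = FALSE] - ref[j, , drop = FALSE])^2))))
    U %*% W + cbind(1, pts) %*% A
  }

  structure(list(warp = warp, W = W, A = A, ref = ref, target = target,
                 bending_energy = be),
            class = "tps_warp")
}

#' Bending-energy matrix of a reference configuration
#'
#' Returns the positive semidefinite k x k matrix `B` such that the
#' thin-plate-spline bending energy of a deformation of `ref` into `Y`
#' is `sum_d Y[,d]' B Y[,d]` (zero for affine `Y`). This is the negated
#' upper-left block of the inverse TPS system matrix (see file header for
#' the 3D sign convention).
#'
#' @param ref k x 3 reference coordinates.
#' @return k x k bending-energy matrix.
#' @export
tps_bending_matrix <- function(ref) {
  ref <- as.matrix(ref)
  L <- tps_system(ref)
  Li <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system (coplanar or duplicated points?): ",
         conditionMessage(e), call. = FALSE))
  B <- -Li[seq_len(nrow(ref)), seq_len(nrow(ref)), drop = FALSE]
  (B + t(B)) / 2
}

#' Bending energy of a deformation
#'
#' @param ref reference k x 3 coordinates (or a precomputed bending-energy
#'   matrix from [tps_bending_matrix()]).
#' @param target deformed k x 3 coordinates.
#' @return non-negative bending energy (0 for affine deformations).
#' @export
bending_energy <- function(ref, target) {
  B <- if (is.matrix(ref) && nrow(ref) == ncol(ref) &&
           nrow(ref) == nrow(as.matrix(target))) ref else tps_bending_matrix(ref)
  Y <- as.matrix(target)
  sum(vapply(seq_len(ncol(Y)), function(d) drop(Y[, d] %*% B %*% Y[, d]), 0))
}

#' Estimate missing landmarks by thin-plate-spline warping
#'
#' Fits a TPS warp from the reference onto the target using the landmarks
#' present in both, then maps the reference positions of the target's missing
#' landmarks through that warp. When the shared landmarks differ only by an
#' affine (e.g. rigid) transform, the missing points are recovered exactly.
#'
#' @param reference a complete `landmark_config` (no missing landmarks).
#' @param target a `landmark_config` with a `missing` mask.
#' @return `target` with all landmarks filled in and the mask cleared.
#' @export
estimate_missing <- function(reference, target) {
  stop_if(!any(target$missing), "target has no missing landmarks")
  stop_if(any(reference$missing), "reference must be complete")
  shared <- which(!target$missing)
  stop_if(length(shared) < 5, "estimation needs at least 5 shared landmarks")
  fit <- tps_fit(reference$coords[shared, , drop = FALSE],
                 target$coords[shared, , drop = FALSE])
  miss <- which(target$missing)
  out <- target
  out$coords[miss, ] <- fit$warp(reference$coords[miss, , drop = FALSE])
  out$missing[] <- FALSE
  out
}
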