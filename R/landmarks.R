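#' Landmark configurations
#'
#' A landmark configuration stores named 3D points (mm) together with the
#' semilandmark-curve scheme and the bone each landmark belongs to. Curve
#' definitions are ordered landmark-index vectors whose first and last entries
#' are fixed landmarks; interior entries are sliding semilandmarks. Every
#' landmark belongs to exactly one bone and to at most one curve.
#'
#' @param coords numeric k x 3 matrix of coordinates (mm); rownames are used
#'   as landmark labels when `labels` is missing.
#' @param curves named list of integer vectors, each an ordered path of row
#'   indices into `coords` (endpoints fixed, interior sliding).
#' @param bone character vector of length k naming the bone of each landmark.
#' @param side `"left"` or `"right"`.
#' @param missing logical mask of length k; `TRUE` marks landmarks that were
#'   not digitized (e.g. clavicula landmarks in clavicula-less species).
#' @param labels optional character vector of landmark names.
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(coords, curves = list(), bone = NULL,
                            side = "left", missing = NULL, labels = NULL) {
  coords <- as.matrix(coords)
  stop_if(ncol(coords) != 3, "coords must be a k x 3 matrix")
  k <- nrow(coords)
  if (!is.null(labels)) rownames(coords) <- labels
  if (is.null(rownames(coords))) rownames(coords) <- sprintf("lm%03d", seq_len(k))
  bone <- bone %||% rep("unassigned", k)
  stop_if(length(bone) != k, "bone must have one entry per landmark")
  missing <- missing %||% rep(FALSE, k)
  stop_if(length(missing) != k, "missing mask must have one entry per landmark")
  side <- match.arg(side, c("left", "right"))

  interior <- integer(0)
  for (nm in names(curves)) {
    idx <- curves[[nm]]
    stop_if(length(idx) < 3, "curve '", nm, "' needs at least 3 points")
    stop_if(any(idx < 1 | idx > k), "curve '", nm, "' indexes outside the configuration")
    inner <- idx[-c(1, length(idx))]
    stop_if(any(inner %in% interior), "a landmark may slide on at most one curve")
    interior <- c(interior, inner)
  }

  structure(list(coords = coords, curves = curves, bone = bone, side = side,
                 missing = missing),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("landmark_config: %d landmarks (%d sliding on %d curves), side %s\n",
              nrow(x$coords), length(semilandmark_indices(x)), length(x$curves), x$side))
  if (any(x$missing)) cat(sprintf("  %d landmarks flagged missing\n", sum(x$missing)))
  invisible(x)
}

#' Indices of sliding semilandmarks (curve interiors)
#' @param config a `landmark_config`.
#' @return integer vector of row indices.
#' @export
semilandmark_indices <- function(config) {
  sort(unique(unlist(lapply(config$curves, function(idx) idx[-c(1, length(idx))]))))
}

#' Indices of fixed landmarks (everything that does not slide)
#' @param config a `landmark_config`.
#' @return integer vector of row indices.
#' @export
fixed_indices <- function(config) {
  setdiff(seq_len(nrow(config$coords)), semilandmark_indices(config))
}

#' Centroid size of a configuration
#'
#' The square root of the summed squared distances of all landmarks to their
#' centroid; the standard size measure of geometric morphometrics. Returns 0
#' when all points coincide (log-size users must reject that case).
#'
#' @param config a `landmark_config` or a k x 3 coordinate matrix.
#' @return centroid size (mm).
#' @export
centroid_size <- function(config) {
  x <- if (inherits(config, "landmark_config")) config$coords else as.matrix(config)
  stop_if(inherits(config, "landmark_config") && any(config$missing),
          "centroid size is undefined while landmarks are missing; estimate them first")
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2, ctr)^2))
}

#' Mirror a right-side configuration to the left
#'
#' Reflects coordinates across one coordinate plane and relabels the side,
#' so left and right girdle halves can be analyzed together. Curve orders and
#' bone memberships are preserved; mirroring twice restores the original.
#'
#' @param config a `landmark_config` with `side == "right"`.
#' @param plane coordinate plane of reflection: `"yz"` (flip x), `"xz"`
#'   (flip y) or `"xy"` (flip z).
#' @return the mirrored `landmark_config` (side `"left"`).
#' @export
mirror_config <- function(config, plane = c("yz", "xz", "xy")) {
  plane <- match.arg(plane)
  axis <- switch(plane, yz = 1L, xz = 2L, xy = 3L)
  out <- config
  out$coords[, axis] <- -out$coords[, axis]
  out$side <- if (config$side == "right") "left" else "right"
  out
}
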