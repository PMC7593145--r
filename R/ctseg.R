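# Micro-CT bone segmentation: calibrated gray windowing, slicewise local
# thresholding along three orthogonal reslicings, 2-of-3 voting, and
# morphological cleanup.

#' Calibrate the gray-value window of a CT volume
#'
#' From a rough bone segmentation and a soft-tissue mask, computes the mean
#' gray value `m` over bone-and-soft voxels and centers the display window
#' at `t = 1.019 * m - 462.812` (an empirical calibration in native CT gray
#' units). The half-width `h = t - q` is the largest symmetric window whose
#' lower limit clips at most a `clip_quantile` fraction of bone voxels to
#' black (`q` is that quantile of the bone grays).
#'
#' @param volume 3D gray array or a `ct_phantom`.
#' @param bone_mask,soft_mask logical arrays (disjoint, non-empty).
#' @param clip_quantile bone-voxel quantile allowed below the window
#'   (default 0.001, i.e. 0.1 percent).
#' @return a `gray_calibration`: `m`, `center`, `half_width`, `window`
#'   (limits), `soft_sd`.
#' @export
calibrate_window <- function(volume, bone_mask, soft_mask,
                             clip_quantile = 0.001) {
  vol <- if (inherits(volume, "ct_phantom")) volume$volume else volume
  stop_if(!any(bone_mask) || !any(soft_mask), "masks must be non-empty")
  stop_if(any(bone_mask & soft_mask), "bone and soft masks must be disjoint")
  m <- mean(vol[bone_mask | soft_mask])
  center <- 1.019 * m - 462.812
  rng <- range(vol)
  stop_if(center <= rng[1] || center >= rng[2],
          "calibration failure: window center ", format(center),
          " falls outside the data range [", rng[1], ", ", rng[2], "]")
  q <- stats::quantile(vol[bone_mask], clip_quantile, names = FALSE)
  h <- center - q
  stop_if(h <= 0, "calibration failure: degenerate window (half-width ",
          format(h), ")")
  structure(list(m = m, center = center, half_width = h,
                 window = c(center - h, center + h),
                 soft_sd = stats::sd(vol[soft_mask])),
            class = "gray_calibration")
}

#' @export
print.gray_calibration <- function(x, ...) {
  cat(sprintf("gray_calibration: m = %.3f, center = %.3f, window [%.3f, %.3f]\n",
              x$m, x$center, x$window[1], x$window[2]))
  invisible(x)
}

#' Rescale a volume to a calibrated gray window
#'
#' Grays at or below the lower window limit map to 0 (black), at or above
#' the upper limit to 65535, linearly in between.
#'
#' @param volume 3D gray array.
#' @param calib a `gray_calibration`.
#' @return rescaled numeric array in `[0, 65535]`.
#' @export
window_rescale <- function(volume, calib) {
  lo <- calib$window[1]; hi <- calib$window[2]
  v <- (volume - lo) / (hi - lo)
  array(pmin(pmax(v, 0), 1) * 65535, dim(volume))
}

# Local mean and SD over a (2r+1)^2 window per 2D slice via integral
# images; windows are clipped at the slice borders.
local_stats_2d <- function(img, r) {
  nx <- nrow(img); ny <- ncol(img)
  pad_cum <- function(m) {
    cs <- apply(m, 2, cumsum)
    t(apply(cs, 1, cumsum))
  }
  S1 <- pad_cum(img); S2 <- pad_cum(img^2)
  at <- function(S, i, j) {
    v <- matrix(0, length(i), length(j))
    ok_i <- i >= 1; ok_j <- j >= 1
    ii <- pmin(pmax(i, 1), nx); jj <- pmin(pmax(j, 1), ny)
    v[ok_i, ok_j] <- S[ii[ok_i], jj[ok_j], drop = FALSE]
    v
  }
  i <- seq_len(nx); j <- seq_len(ny)
  i2 <- pmin(i + r, nx); i1 <- i - r - 1
  j2 <- pmin(j + r, ny); j1 <- j - r - 1
  box <- function(S) at(S, i2, j2) - at(S, i1, j2) - at(S, i2, j1) + at(S, i1, j1)
  cnt <- outer(i2 - pmax(i1, 0), j2 - pmax(j1, 0))
  mu <- box(S1) / cnt
  va <- pmax(box(S2) / cnt - mu^2, 0)
  list(mean = mu, sd = sqrt(va))
}

# Slicewise Niblack thresholding along one axis of a 3D volume.
# A voxel passes when it reaches the local Niblack level (mean + k * SD,
# non-strict so homogeneous bright windows stay foreground) AND a global
# class-separation floor. The floor guards object-free windows, where the
# local rule alone marks ~half the noise as foreground (the classic
# Niblack failure mode).
threshold_along <- function(vol, axis, radius, k, floor_val) {
  out <- array(FALSE, dim(vol))
  n <- dim(vol)[axis]
  for (s in seq_len(n)) {
    sl <- switch(axis, vol[s, , ], vol[, s, ], vol[, , s])
    st <- local_stats_2d(sl, radius)
    bin <- sl >= st$mean + k * st$sd & sl >= floor_val
    switch(axis, out[s, , ] <- bin, out[, s, ] <- bin, out[, , s] <- bin)
  }
  out
}

#' Otsu threshold of a gray-value sample
#'
#' Maximizes between-class variance over a binned histogram.
#'
#' @param x numeric vector (or array) of gray values.
#' @param n_bins histogram resolution.
#' @return threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.vector(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h); tot <- w[n_bins]
  mu <- cumsum(h * mids); mu_t <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- tot - w0
  ok <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, n_bins - 1)
  bc[ok] <- (mu_t * w0[ok] / tot - mu[-n_bins][ok])^2 * tot^2 /
    (w0[ok] * w1[ok])
  mids[which.max(bc)]
}

shift_array <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- idx[[axis]] - by
  pad <- src < 1 | src > d[axis]
  src <- pmin(pmax(src, 1), d[axis])
  idx[[axis]] <- src
  out <- do.call(`[`, c(list(a), idx))
  # padded positions take the border value (replicate padding)
  out
}

morph_op <- function(mask, radius, op) {
  out <- mask
  for (axis in 1:3) {
    acc <- out
    for (b in seq_len(radius)) {
      acc <- if (op == "dilate")
        acc | shift_array(out, axis, b) | shift_array(out, axis, -b)
      else
        acc & shift_array(out, axis, b) & shift_array(out, axis, -b)
    }
    out <- acc
  }
  out
}

#' Segment bone by local thresholding and 2-of-3 voting
#'
#' The (optionally window-rescaled) volume is thresholded slicewise by a 2D
#' local method (Niblack: pixel is bone when its gray exceeds the local
#' window mean plus `k` local SDs) along each of the three orthogonal axes
#' (original orientation plus two reslicings). A voxel is bone when at
#' least two of the three thresholded stacks classify it as bone. The vote
#' is intersected with the rough mask (when given) and closed
#' morphologically (automated stand-in for manual foramen filling).
#'
#' @param volume 3D gray array or `ct_phantom`.
#' @param calib optional `gray_calibration` for window rescaling before
#'   thresholding (`NULL` skips windowing, e.g. for data outside the
#'   calibration formula's native gray range).
#' @param rough_mask optional logical array restricting the result.
#' @param radius local-threshold window radius (pixels).
#' @param k Niblack SD multiplier.
#' @param floor_val global gray floor a bone voxel must also reach;
#'   `"auto"` (default) uses the midpoint of the global two-class (Otsu)
#'   class means, which silences object-free windows while leaving mixed
#'   windows split by the local statistics. Use `-Inf` for the plain local
#'   rule.
#' @param close_radius radius of the morphological closing; 0 disables.
#' @return a `segmentation`: logical `mask`, the three per-axis vote
#'   inputs' bone fractions, and the method parameters.
#' @export
segment_vote <- function(volume, calib = NULL, rough_mask = NULL,
                         radius = 15, k = 0.2, floor_val = "auto",
                         close_radius = 1) {
  vol <- if (inherits(volume, "ct_phantom")) volume$volume else volume
  vol <- vol * 1.0
  if (!is.null(calib)) vol <- window_rescale(vol, calib)
  if (identical(floor_val, "auto")) {
    th <- otsu_threshold(vol)
    floor_val <- (mean(vol[vol > th]) + mean(vol[vol <= th])) / 2
    if (!is.finite(floor_val)) floor_val <- -Inf
  }
  stacks <- lapply(1:3, function(ax)
    threshold_along(vol, ax, radius, k, floor_val))
  mask <- vote_majority(stacks[[1]], stacks[[2]], stacks[[3]])
  if (!is.null(rough_mask)) mask <- mask & rough_mask
  if (close_radius > 0) {
    mask <- morph_op(mask, close_radius, "dilate")
    mask <- morph_op(mask, close_radius, "erode")
  }
  if (!any(mask)) warning("empty segmentation: no voxel classified as bone")
  structure(list(mask = mask,
                 axis_bone_fraction = vapply(stacks, mean, 0),
                 method = "niblack", radius = radius, k = k,
                 floor_val = floor_val,
                 close_radius = close_radius, windowed = !is.null(calib)),
            class = "segmentation")
}

#' Dilate a binary mask (box structuring element)
#'
#' Convenience for building rough masks around a segmentation.
#'
#' @param mask logical 3D array.
#' @param radius dilation radius (voxels).
#' @return dilated logical array.
#' @export
dilate_mask <- function(mask, radius = 1) morph_op(mask, radius, "dilate")

#' 2-of-3 majority vote of binary masks
#' @param a,b,c logical arrays of identical shape.
#' @return logical array, `TRUE` where at least two inputs are `TRUE`.
#' @export
vote_majority <- function(a, b, c) {
  (a & b) | (a & c) | (b & c)
}

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks are defined as
#' identical (Dice 1).
#'
#' @param mask_a,mask_b logical arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  stop_if(!identical(dim(mask_a), dim(mask_b)), "mask shapes differ")
  sa <- sum(mask_a); sb <- sum(mask_b)
  if (sa + sb == 0) return(1)
  2 * sum(mask_a & mask_b) / (sa + sb)
}
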