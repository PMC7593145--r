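# Anatomical coordinate frame, two-axis shoulder joint, hypothetical
# muscles, and tendon-excursion moment arms.
#
# Frame convention: origin at the glenoid joint center; x mediolateral
# (lateral, toward the left limb, positive); y dorsoventral (dorsal
# positive); z anteroposterior (anterior positive). The y-z plane is
# parallel to the sagittal plane and the line from the anteromedial
# clavicula tip to the posteromedial coracoid tip is parallel to the x-z
# plane.
#
# Joint convention: reference pose = humerus long axis along +x.
# Protraction/retraction rotates about +y (positive angle = retraction,
# i.e. the humerus swings posteriorly); adduction/abduction rotates about
# -z (positive angle = adduction, the humerus swings ventrally). The
# protraction/retraction rotation is applied first, then
# adduction/abduction. Positive moment arms mean retraction (pr axis) or
# adduction (aa axis).

#' Build the anatomical coordinate frame from named points
#'
#' Constructs the rigid transform into the anatomical frame: the origin at
#' the glenoid center; z along the specimen midline (anterior positive);
#' the y-z plane parallel to the sagittal plane (which contains the two
#' midline witness points); and the roll about the midline chosen so the
#' line connecting the anteromedial clavicula tip to the posteromedial
#' coracoid tip is parallel to the x-z plane. Two midline witness points
#' are required because a single point does not pin down the sagittal
#' plane.
#'
#' @param named_points matrix with (at least) rows `glenoid_center`,
#'   `anteromedial_clavicula_tip`, `posteromedial_coracoid_tip`,
#'   `episternum_anterior_tip` (anterior midline witness) and
#'   `sternum_posterior_tip` (posterior midline witness).
#' @return an `anatomical_frame`: rotation `R` (rows = frame axes in world
#'   coordinates), `origin`, constraint `residuals`, and helpers
#'   `to_frame(pts)` / `to_world(pts)`.
#' @export
build_frame <- function(named_points) {
  need <- c("glenoid_center", "anteromedial_clavicula_tip",
            "posteromedial_coracoid_tip", "episternum_anterior_tip",
            "sternum_posterior_tip")
  stop_if(!all(need %in% rownames(named_points)),
          "named_points must contain: ", paste(need, collapse = ", "))
  g <- named_points["glenoid_center", ]
  a <- named_points["anteromedial_clavicula_tip", ]
  pc <- named_points["posteromedial_coracoid_tip", ]
  w_ant <- named_points["episternum_anterior_tip", ]
  w_post <- named_points["sternum_posterior_tip", ]

  z <- tryCatch(unit_vec(w_ant - w_post), error = function(e)
    stop("degenerate midline witnesses (coincident points)", call. = FALSE))
  # orthonormal basis perpendicular to z
  h <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit_vec(cross3(h, z)); v <- cross3(z, u)
  d <- pc - a
  # x(theta) = cos t * u + sin t * v ; require d . y = d . (z x x) = 0
  cu <- sum(d * cross3(z, u)); cv <- sum(d * cross3(z, v))
  stop_if(abs(cu) + abs(cv) < 1e-12,
          "clavicula-coracoid line is parallel to the midline; frame underdetermined")
  theta <- atan2(-cu, cv)
  x <- cos(theta) * u + sin(theta) * v
  # of the two solutions pick x pointing laterally (from midline toward glenoid)
  if (sum((g - (w_ant + w_post) / 2) * x) < 0) x <- -x
  y <- cross3(z, x)
  R <- rbind(x = x, y = y, z = z)

  to_frame <- function(pts) {
    pts <- rbind(as.matrix(pts))
    sweep(pts, 2, g) %*% t(R)
  }
  to_world <- function(pts) {
    pts <- rbind(as.matrix(pts))
    sweep(pts %*% R, 2, -g)
  }
  af <- sum(d * y)                       # should be ~0
  wf <- to_frame(rbind(w_ant, w_post))
  residuals <- c(line_y_component = abs(af),
                 witness_x_spread = abs(diff(wf[, 1])))
  structure(list(R = R, origin = g, residuals = residuals,
                 to_frame = to_frame, to_world = to_world,
                 midline_x = mean(wf[, 1]), midline_y = mean(wf[, 2])),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("anatomical_frame: origin", sprintf("(%.3g, %.3g, %.3g)", x$origin[1],
                                          x$origin[2], x$origin[3]), "\n")
  cat(sprintf("  constraint residuals: line-y %.2e, witness-x %.2e\n",
              x$residuals[1], x$residuals[2]))
  invisible(x)
}

#' Define the hypothetical shoulder muscles
#'
#' Builds the muscle set of the biomechanical model: `anterior` (origin at
#' the anteromedial clavicula tip), `perpendicular` (origin on the ventral
#' midline at the insertion's anteroposterior level, so its line is
#' perpendicular to the long axis in the reference pose) and `posterior`
#' (origin at the posteromedial coracoid tip) are always present; with
#' `has_episternum`/`has_sternum`, muscles originating from the episternum
#' anterior tip / sternum posterior tip are added. All muscles insert at a
#' common point 40% (by default) along the simplified humerus.
#'
#' @param frame an `anatomical_frame`.
#' @param named_points matrix of anatomical points (world coordinates).
#' @param has_sternum,has_episternum include the optional muscles?
#' @param humerus_length simplified humerus length (mm).
#' @param insertion_frac insertion position as a fraction of humerus length.
#' @return a `muscle_model`: list of muscle paths (each with `name`,
#'   girdle-fixed `origin` and `via` points in frame coordinates, and the
#'   humerus-fixed `insertion_local`), plus the frame and joint settings.
#' @export
build_default_muscles <- function(frame, named_points, has_sternum = FALSE,
                                  has_episternum = FALSE, humerus_length = 5,
                                  insertion_frac = 0.4) {
  pf <- frame$to_frame(named_points)
  rownames(pf) <- rownames(named_points)
  insertion_local <- c(insertion_frac * humerus_length, 0, 0)
  mk <- function(name, origin) list(name = name, origin = origin,
                                    via = matrix(0, 0, 3),
                                    insertion_local = insertion_local)
  need <- function(nm) {
    stop_if(!nm %in% rownames(pf), "named point '", nm,
            "' required for the requested muscles")
    pf[nm, ]
  }
  perp_origin <- c(frame$midline_x, frame$midline_y, insertion_local[3])
  muscles <- list(
    mk("anterior", need("anteromedial_clavicula_tip")),
    mk("perpendicular", perp_origin),
    mk("posterior", need("posteromedial_coracoid_tip")))
  if (has_sternum) muscles <- c(muscles, list(mk("sternal", need("sternum_posterior_tip"))))
  if (has_episternum) muscles <- c(muscles, list(mk("episternal", need("episternum_anterior_tip"))))
  names(muscles) <- vapply(muscles, `[[`, "", "name")
  structure(list(muscles = muscles, frame = frame,
                 humerus_length = humerus_length,
                 insertion_frac = insertion_frac),
            class = "muscle_model")
}

# Pose transform: humerus-local -> frame coordinates.
pose_rotation <- function(theta_pr, theta_aa) {
  rot_z(-theta_aa) %*% rot_y(theta_pr)
}

muscle_path_points <- function(muscle, theta_pr = 0, theta_aa = 0) {
  p <- drop(pose_rotation(theta_pr, theta_aa) %*% muscle$insertion_local)
  rbind(muscle$origin, muscle$via, insertion = p)
}

muscle_path_length <- function(muscle, theta_pr = 0, theta_aa = 0) {
  pts <- muscle_path_points(muscle, theta_pr, theta_aa)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Muscle moment arm about a shoulder-joint axis
#'
#' Geometric moment arm of the humerus-side muscle segment:
#' `r = ((p - c) x f) . a`, where `p` is the insertion at the given pose,
#' `c` the joint center, `f` the unit vector from the insertion toward the
#' last girdle-fixed path point, and `a` the joint axis (+y for
#' protraction/retraction, -z for adduction/abduction). By the
#' tendon-excursion principle this equals minus the derivative of total
#' path length with respect to the joint angle. Positive values mean
#' retraction (pr) or adduction (aa).
#'
#' @param muscle one muscle from a [build_default_muscles()] model.
#' @param axis `"pr"` or `"aa"`.
#' @param theta_pr,theta_aa pose angles (radians).
#' @return moment arm (mm, signed).
#' @export
moment_arm <- function(muscle, axis = c("pr", "aa"), theta_pr = 0,
                       theta_aa = 0) {
  axis <- match.arg(axis)
  # pr is applied before aa, so its axis is carried along by the aa rotation;
  # the aa axis (applied last) stays fixed in the frame
  a_vec <- if (axis == "pr") drop(rot_z(-theta_aa) %*% c(0, 1, 0)) else c(0, 0, -1)
  p <- drop(pose_rotation(theta_pr, theta_aa) %*% muscle$insertion_local)
  q <- if (nrow(muscle$via) > 0) muscle$via[nrow(muscle$via), ] else muscle$origin
  seg <- q - p
  len <- sqrt(sum(seg^2))
  stop_if(len < 1e-12, "zero-length final muscle segment: moment arm undefined")
  f <- seg / len
  sum(cross3(p, f) * a_vec)
}

# Finite-difference tendon-excursion moment arm (independent route used in
# verification): -dL/dtheta by central differences.
moment_arm_fd <- function(muscle, axis = c("pr", "aa"), theta_pr = 0,
                          theta_aa = 0, h = 1e-4) {
  axis <- match.arg(axis)
  if (axis == "pr") {
    lp <- muscle_path_length(muscle, theta_pr + h, theta_aa)
    lm <- muscle_path_length(muscle, theta_pr - h, theta_aa)
  } else {
    lp <- muscle_path_length(muscle, theta_pr, theta_aa + h)
    lm <- muscle_path_length(muscle, theta_pr, theta_aa - h)
  }
  -(lp - lm) / (2 * h)
}

#' Sweep moment arms over a range of humerus positions
#'
#' Samples the moment arm of every muscle of a model over an angle grid
#' (the non-swept joint angle held at 0), derives the action ranges (where
#' the muscle retracts vs protracts, or adducts vs abducts) and the zero
#' crossings (bracketed by sign changes on the grid, located by linear
#' interpolation).
#'
#' @param model a `muscle_model`.
#' @param axis_of optional named character vector muscle -> axis; defaults
#'   to `"aa"` for the perpendicular muscle and `"pr"` for all others.
#' @param range sweep limits in degrees.
#' @param step grid step in degrees.
#' @return a `moment_arm_curves` object: `curves` data frame (muscle, axis,
#'   angle_deg, moment_arm_mm), `zero_crossings`, `action_ranges`.
#' @export
sweep_moment_arms <- function(model, axis_of = NULL, range = c(-75, 75),
                              step = 5) {
  stop_if(!inherits(model, "muscle_model"), "need a muscle_model")
  angles <- seq(range[1], range[2], by = step)
  out <- NULL; zc <- list(); ar <- list()
  for (m in model$muscles) {
    ax <- if (!is.null(axis_of) && m$name %in% names(axis_of))
      axis_of[[m$name]] else if (m$name == "perpendicular") "aa" else "pr"
    r <- vapply(angles, function(th) {
      tryCatch(
        if (ax == "pr") moment_arm(m, "pr", theta_pr = th * pi / 180)
        else moment_arm(m, "aa", theta_aa = th * pi / 180),
        error = function(e) NA_real_)
    }, 0)
    out <- rbind(out, data.frame(muscle = m$name, axis = ax,
                                 angle_deg = angles, moment_arm_mm = r))
    s <- sign(r)
    flips <- which(s[-1] * s[-length(s)] < 0)
    zc[[m$name]] <- sort(c(
      angles[!is.na(r) & abs(r) < 1e-12],            # exact grid zeros
      vapply(flips, function(i)
        angles[i] - r[i] * step / (r[i + 1] - r[i]), 0)))
    pos <- angles[!is.na(r) & r > 0]
    ar[[m$name]] <- list(
      positive = if (length(pos)) c(min(pos), max(pos)) else NULL,
      positive_width = length(pos) * step,
      positive_meaning = if (ax == "pr") "retraction" else "adduction")
  }
  structure(list(curves = out, zero_crossings = zc, action_ranges = ar,
                 step = step), class = "moment_arm_curves")
}

#' @export
print.moment_arm_curves <- function(x, ...) {
  cat("moment-arm curves:\n")
  for (m in unique(x$curves$muscle)) {
    sub <- x$curves[x$curves$muscle == m, ]
    at0 <- sub$moment_arm_mm[sub$angle_deg == 0]
    cat(sprintf("  %-13s (%s): %6.3f mm at reference, %s zero crossing(s)\n",
                m, sub$axis[1], at0, length(x$zero_crossings[[m]])))
  }
  invisible(x)
}

#' Check a muscle path for intersections with bone surfaces
#'
#' Straight path segments are tested against every mesh triangle
#' (Moller-Trumbore). Intersections are reported, not resolved; girdle-fixed
#' via points are the supported way to route a path around bone.
#'
#' @param muscle a muscle path (frame coordinates).
#' @param meshes list of `tri_mesh` objects in frame coordinates.
#' @param theta_pr,theta_aa pose.
#' @return number of intersected triangles.
#' @export
check_path_intersections <- function(muscle, meshes, theta_pr = 0,
                                     theta_aa = 0) {
  pts <- muscle_path_points(muscle, theta_pr, theta_aa)
  hits <- 0L
  for (s in seq_len(nrow(pts) - 1)) {
    o <- pts[s, ]; d <- pts[s + 1, ] - pts[s, ]
    for (mesh in meshes) {
      v <- mesh$vertices; f <- mesh$faces
      for (i in seq_len(nrow(f))) {
        e1 <- v[f[i, 2], ] - v[f[i, 1], ]
        e2 <- v[f[i, 3], ] - v[f[i, 1], ]
        pv <- cross3(d, e2)
        det <- sum(e1 * pv)
        if (abs(det) < 1e-12) next
        tv <- o - v[f[i, 1], ]
        u <- sum(tv * pv) / det
        if (u < 0 || u > 1) next
        qv <- cross3(tv, e1)
        w <- sum(d * qv) / det
        if (w < 0 || u + w > 1) next
        t <- sum(e2 * qv) / det
        if (t > 1e-9 && t < 1 - 1e-9) hits <- hits + 1L
      }
    }
  }
  hits
}
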