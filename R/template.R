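# Stylized left pectoral girdle template.
#
# Canonical pose: origin at the glenoid (shoulder joint) center, x lateral
# (toward the left limb), y dorsal, z anterior; the specimen midline lies in
# a plane x = const < 0 medial of the girdle. The template is a geometric
# caricature of the anuran pectoral girdle, not a homology claim: it carries
# the landmark scheme of the analysis (19 fixed landmarks; nine curves of
# sliding semilandmarks; four bones) and the named anatomical points the
# biomechanical models need, with all proportions exposed as parameters.

bezier2 <- function(p0, p1, ctrl, t) {
  outer((1 - t)^2, p0) + outer(2 * t * (1 - t), ctrl) + outer(t^2, p1)
}

#' Stylized girdle landmark template
#'
#' Builds the template `landmark_config` (19 fixed landmarks and nine curves
#' of sliding semilandmarks across scapula, coracoid, cleithrum, clavicula)
#' plus the named anatomical points used by the frame/muscle/FEA modules.
#'
#' @param scapula_height,scapula_width blade dimensions (mm).
#' @param coracoid_length,coracoid_width coracoid rod dimensions (mm).
#' @param coracoid_angle posterior tilt of the coracoid long axis against the
#'   mediolateral axis (degrees).
#' @param clavicula_curvature anterior bow of the clavicula (fraction of its
#'   chord length).
#' @param glenoid_position ventral-margin height of the scapula above the
#'   glenoid center (mm).
#' @param semis_per_curve semilandmarks per curve (21-29 by scheme; 25 by
#'   default).
#' @return an object of class `girdle_template`: list with the template
#'   `config`, `named_points` (matrix with rows glenoid_center,
#'   anteromedial_clavicula_tip, posteromedial_coracoid_tip,
#'   coracoid_anteromedial_tip, sternum_posterior_tip,
#'   episternum_anterior_tip), and the parameter list.
#' @export
girdle_template <- function(scapula_height = 8, scapula_width = 5,
                            coracoid_length = 7, coracoid_width = 2.5,
                            coracoid_angle = 20, clavicula_curvature = 0.35,
                            glenoid_position = 0.8, semis_per_curve = 25) {
  stop_if(any(c(scapula_height, scapula_width, coracoid_length,
                coracoid_width) <= 0), "template dimensions must be positive")
  stop_if(semis_per_curve < 21 || semis_per_curve > 29,
          "semis_per_curve must lie in the scheme's 21-29 range")
  hs <- scapula_height; ws <- scapula_width
  lc <- coracoid_length; wc <- coracoid_width
  al <- coracoid_angle * pi / 180
  gp <- glenoid_position
  axis_c <- c(-cos(al), 0, -sin(al))            # coracoid long axis, medially
  perp_c <- c(-sin(al), 0, cos(al))             # in-plane normal, anteriorly
  m_c <- c(0, -0.2, 0) + coracoid_length * axis_c   # medial end of coracoid

  fixed <- rbind(
    sc_ventral_anterior  = c(0.4, gp, ws / 2 - 0.3),
    sc_dorsal_anterior   = c(1.2, gp + hs, ws / 2 - 0.5),
    sc_dorsal_posterior  = c(1.2, gp + hs, -(ws / 2 - 0.5)),
    sc_ventral_posterior = c(0.4, gp, -(ws / 2 - 0.3)),
    sc_glenoid           = c(0.15, 0.4, -0.5),
    sc_blade_center      = c(0.8, gp + hs / 2, 0.3),
    co_glenoid           = c(0, 0, 0),
    co_anterolateral     = c(-0.6, -0.15, 1.1),
    co_posterolateral    = c(-0.6, -0.25, -1.3),
    co_anteromedial_tip  = m_c + perp_c * wc / 2,
    co_posteromedial_tip = m_c - perp_c * wc / 2,
    co_shaft_center      = m_c / 2 + c(0, 0.3, 0.2),
    cl_lateral           = c(-0.2, 0.3, 0.7),
    # dorsoventral level matches the coracoid tips so the clavicula-tip to
    # coracoid-tip line is parallel to the x-z plane in canonical pose
    cl_anteromedial_tip  = c(-(lc * cos(al) + 0.52), -0.2, 1.6),
    cl_shaft_dorsal      = c(0, 0, 0),          # placed below, on the arc
    ce_anterior          = c(1.2, gp + hs + 0.4, ws / 2 - 0.5),
    ce_posterior         = c(1.2, gp + hs + 0.4, -(ws / 2 - 0.5)),
    ce_dorsal            = c(1.2, gp + hs + 1.1, 0.05),
    ce_lateral           = c(1.45, gp + hs + 0.2, 0.6))

  cl_chord <- fixed["cl_anteromedial_tip", ] - fixed["cl_lateral", ]
  cl_ctrl <- fixed["cl_lateral", ] + cl_chord / 2 +
    c(0, 0, clavicula_curvature * sqrt(sum(cl_chord^2)) / 2)
  fixed["cl_shaft_dorsal", ] <-
    drop(bezier2(fixed["cl_lateral", ], fixed["cl_anteromedial_tip", ],
                 cl_ctrl, 0.5)) + c(0, 0.4, 0)

  bone_fixed <- rep(c("scapula", "coracoid", "clavicula", "cleithrum"),
                    times = c(6, 6, 3, 4))

  bulge <- function(a, b, off) (fixed[a, ] + fixed[b, ]) / 2 + off
  curve_defs <- list(
    sc_anterior_margin  = list("sc_ventral_anterior", "sc_dorsal_anterior",
                               bulge("sc_ventral_anterior", "sc_dorsal_anterior", c(0, 0, 0.8)), "scapula"),
    sc_dorsal_margin    = list("sc_dorsal_anterior", "sc_dorsal_posterior",
                               bulge("sc_dorsal_anterior", "sc_dorsal_posterior", c(0, 0.8, 0)), "scapula"),
    sc_posterior_margin = list("sc_dorsal_posterior", "sc_ventral_posterior",
                               bulge("sc_dorsal_posterior", "sc_ventral_posterior", c(0, 0, -0.8)), "scapula"),
    sc_ventral_margin   = list("sc_ventral_posterior", "sc_ventral_anterior",
                               bulge("sc_ventral_posterior", "sc_ventral_anterior", c(0, -0.3, 0)), "scapula"),
    co_anterior_margin  = list("co_anterolateral", "co_anteromedial_tip",
                               bulge("co_anterolateral", "co_anteromedial_tip", c(0, 0, 0.5)), "coracoid"),
    co_posterior_margin = list("co_posterolateral", "co_posteromedial_tip",
                               bulge("co_posterolateral", "co_posteromedial_tip", c(0, 0, -0.5)), "coracoid"),
    co_medial_margin    = list("co_anteromedial_tip", "co_posteromedial_tip",
                               m_c + c(-0.5, 0, 0), "coracoid"),
    cl_shaft            = list("cl_lateral", "cl_anteromedial_tip", cl_ctrl, "clavicula"),
    ce_shaft            = list("ce_anterior", "ce_posterior",
                               c(1.2, gp + hs + 1.35, 0), "cleithrum"))

  nsl <- semis_per_curve
  tt <- seq_len(nsl) / (nsl + 1)
  coords <- fixed
  bone <- bone_fixed
  curves <- list()
  for (nm in names(curve_defs)) {
    cd <- curve_defs[[nm]]
    i0 <- match(cd[[1]], rownames(fixed)); i1 <- match(cd[[2]], rownames(fixed))
    pts <- bezier2(fixed[i0, ], fixed[i1, ], cd[[3]], tt)
    rownames(pts) <- sprintf("%s_s%02d", nm, seq_len(nsl))
    start <- nrow(coords)
    coords <- rbind(coords, pts)
    bone <- c(bone, rep(cd[[4]], nsl))
    curves[[nm]] <- c(i0, start + seq_len(nsl), i1)
  }

  named_points <- rbind(
    glenoid_center             = c(0, 0, 0),
    anteromedial_clavicula_tip = fixed["cl_anteromedial_tip", ],
    posteromedial_coracoid_tip = fixed["co_posteromedial_tip", ],
    coracoid_anteromedial_tip  = fixed["co_anteromedial_tip", ],
    sternum_posterior_tip      = c(-(lc * cos(al) + 0.47), -0.4, -3.2),
    episternum_anterior_tip    = c(-(lc * cos(al) + 0.47), -0.4, 2.0))

  params <- list(scapula_height = scapula_height, scapula_width = scapula_width,
                 coracoid_length = coracoid_length, coracoid_width = coracoid_width,
                 coracoid_angle = coracoid_angle,
                 clavicula_curvature = clavicula_curvature,
                 glenoid_position = glenoid_position,
                 semis_per_curve = semis_per_curve)
  structure(list(config = landmark_config(coords, curves = curves, bone = bone),
                 named_points = named_points, params = params,
                 internals = list(m_c = m_c, axis_c = axis_c, perp_c = perp_c,
                                  cl_ctrl = cl_ctrl)),
            class = "girdle_template")
}

#' @export
print.girdle_template <- function(x, ...) {
  cat(sprintf("girdle_template: %d landmarks (%d fixed, %d curves x %d semilandmarks)\n",
              nrow(x$config$coords), length(fixed_indices(x$config)),
              length(x$config$curves), x$params$semis_per_curve))
  invisible(x)
}

# ---- triangulated surfaces ---------------------------------------------

# Closed triangulated tube around a polyline path with a diamond
# cross-section (vertices at +/- r_up and +/- r_side), capped by apex
# vertices exactly at the path endpoints extended by apex_at ends.
extrude_tube <- function(path, r_up, r_side, up_hint = c(0, 1, 0),
                         apex_start = NULL, apex_end = NULL) {
  path <- as.matrix(path)
  m <- nrow(path)
  stop_if(m < 2, "tube path needs at least 2 points")
  tangent <- function(i) {
    if (i == 1) unit_vec(path[2, ] - path[1, ])
    else if (i == m) unit_vec(path[m, ] - path[m - 1, ])
    else unit_vec(path[i + 1, ] - path[i - 1, ])
  }
  delta <- 0.4 * min(r_up, r_side)
  apex1 <- apex_start %||% (path[1, ] - delta * tangent(1))
  apex2 <- apex_end %||% (path[m, ] + delta * tangent(m))

  verts <- rbind(apex1)
  for (i in seq_len(m)) {
    t <- tangent(i)
    side <- unit_vec(cross3(up_hint, t))
    up <- cross3(t, side)
    ring <- rbind(path[i, ] + r_up * up, path[i, ] + r_side * side,
                  path[i, ] - r_up * up, path[i, ] - r_side * side)
    verts <- rbind(verts, ring)
  }
  verts <- rbind(verts, apex2)
  ring_idx <- function(i) 1 + (i - 1) * 4 + 1:4
  faces <- NULL
  r1 <- ring_idx(1)
  for (j in 1:4) faces <- rbind(faces, c(1, r1[j %% 4 + 1], r1[j]))
  for (i in seq_len(m - 1)) {
    a <- ring_idx(i); b <- ring_idx(i + 1)
    for (j in 1:4) {
      jn <- j %% 4 + 1
      faces <- rbind(faces, c(a[j], a[jn], b[jn]), c(a[j], b[jn], b[j]))
    }
  }
  rm_ <- ring_idx(m); apx <- nrow(verts)
  for (j in 1:4) faces <- rbind(faces, c(apx, rm_[j], rm_[j %% 4 + 1]))
  mesh <- structure(list(vertices = verts, faces = faces), class = "tri_mesh")
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Signed volume enclosed by a triangle mesh
#' @param mesh a `tri_mesh` (list with `vertices`, `faces`).
#' @return signed enclosed volume (positive for outward-oriented closed
#'   surfaces).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  sum(vapply(seq_len(nrow(f)), function(i) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; d <- v[f[i, 3], ]
    sum(a * cross3(b, d)) / 6
  }, 0))
}

#' Euler characteristic of a triangle mesh
#'
#' Computed as V - E + F with edges counted once; 2 for a closed genus-0
#' surface.
#' @param mesh a `tri_mesh`.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  nrow(mesh$vertices) - nrow(e) + nrow(f)
}

#' Build triangulated bone surfaces for a girdle template
#'
#' Generates one closed, consistently outward-oriented triangle mesh per
#' bone (scapula, coracoid, cleithrum, clavicula) from the template
#' parameters. Named anatomical points that belong to a bone (glenoid
#' center, coracoid tips, clavicula tip) coincide with mesh vertices; the
#' sternum/episternum points lie on the specimen midline and carry no
#' surface.
#'
#' @param template a `girdle_template`.
#' @return list with `meshes` (named list of `tri_mesh`) and `named_points`.
#' @export
make_girdle_assets <- function(template) {
  stop_if(!inherits(template, "girdle_template"), "need a girdle_template")
  p <- template$params
  stop_if(any(unlist(p[c("scapula_height", "scapula_width", "coracoid_length",
                         "coracoid_width")]) <= 0),
          "degenerate template parameters")
  fx <- template$config$coords
  np <- template$named_points
  inn <- template$internals
  gp <- p$glenoid_position; hs <- p$scapula_height; ws <- p$scapula_width

  seg_path <- function(a, b, n = 6) {
    tt <- seq(0, 1, length.out = n)
    outer(1 - tt, a) + outer(tt, b)
  }
  bez_path <- function(a, b, ctrl, n = 12) bezier2(a, b, ctrl, seq(0, 1, length.out = n))

  coracoid <- extrude_tube(seg_path(np["glenoid_center", ], inn$m_c),
                           r_up = 0.8, r_side = p$coracoid_width / 2,
                           apex_start = np["glenoid_center", ])
  clavicula <- extrude_tube(bez_path(fx["cl_lateral", ],
                                     np["anteromedial_clavicula_tip", ],
                                     inn$cl_ctrl),
                            r_up = 0.35, r_side = 0.35,
                            apex_end = np["anteromedial_clavicula_tip", ])
  scapula <- extrude_tube(seg_path(c(0.4, gp, 0), c(1.2, gp + hs, 0)),
                          r_up = 0.45, r_side = ws / 2, up_hint = c(1, 0, 0))
  cleithrum <- extrude_tube(bez_path(fx["ce_anterior", ], fx["ce_posterior", ],
                                     c(1.2, gp + hs + 1.35, 0)),
                            r_up = 0.3, r_side = 0.3, up_hint = c(0, 1, 0))
  list(meshes = list(scapula = scapula, coracoid = coracoid,
                     cleithrum = cleithrum, clavicula = clavicula),
       named_points = np)
}
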