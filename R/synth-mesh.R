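# Structured tetrahedral test meshes with named node/face sets.
#
# A beam of given length x width x height is meshed as a structured
# hexahedral grid, each hex split into six positively oriented tetrahedra.
# An optional curvature parameter shears the beam axis in the x-z plane
# (z += curvature * x^2 / length); being a shear, it preserves the total
# volume exactly. Face sets: end_min/end_max (x faces), side_* (y/z faces).

#' Structured tetrahedral beam mesh
#'
#' @param length,width,height beam dimensions along x, y, z (mm).
#' @param divisions integer vector `c(nx, ny, nz)` of cells per axis.
#' @param curvature transverse offset of the beam axis at `x = length`, as a
#'   fraction of `length` (0 = straight beam). Applied as a volume-preserving
#'   shear in the x-z plane.
#' @return a `tet_mesh`: `nodes` (n x 3), `elems` (m x 4, positive signed
#'   volumes), `node_sets` and `face_sets` (`end_min`, `end_max`,
#'   `side_ymin`, `side_ymax`, `side_zmin`, `side_zmax`).
#' @export
make_tet_beam <- function(length = 10, width = 1, height = 1,
                          divisions = c(10, 2, 2), curvature = 0) {
  stop_if(any(c(length, width, height) <= 0), "beam dimensions must be positive")
  divisions <- as.integer(divisions)
  stop_if(base::length(divisions) != 3 || any(divisions < 1),
          "divisions must be three integers >= 1")
  nx <- divisions[1]; ny <- divisions[2]; nz <- divisions[3]
  xs <- seq(0, length, length.out = nx + 1)
  ys <- seq(-width / 2, width / 2, length.out = ny + 1)
  zs <- seq(-height / 2, height / 2, length.out = nz + 1)
  grid <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  nodes <- as.matrix(grid)
  nodes[, 3] <- nodes[, 3] + curvature * nodes[, 1]^2 / length
  nid <- function(i, j, k) i + (nx + 1) * ((j - 1) + (ny + 1) * (k - 1))

  # 6-tet split of each hex, consistent across the grid
  tet_of_hex <- rbind(c(1, 2, 4, 8), c(1, 2, 8, 6), c(1, 6, 8, 5),
                      c(1, 4, 3, 8), c(1, 3, 7, 8), c(1, 7, 5, 8))
  hex <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz),
                     KEEP.OUT.ATTRS = FALSE)
  corners <- cbind(nid(hex$i, hex$j, hex$k), nid(hex$i + 1, hex$j, hex$k),
                   nid(hex$i, hex$j + 1, hex$k), nid(hex$i + 1, hex$j + 1, hex$k),
                   nid(hex$i, hex$j, hex$k + 1), nid(hex$i + 1, hex$j, hex$k + 1),
                   nid(hex$i, hex$j + 1, hex$k + 1),
                   nid(hex$i + 1, hex$j + 1, hex$k + 1))
  elems <- do.call(rbind, lapply(1:6, function(t)
    corners[, tet_of_hex[t, ], drop = FALSE]))
  storage.mode(elems) <- "integer"
  # enforce positive signed volumes
  vols <- tet_volumes(nodes, elems)
  flip <- vols < 0
  if (any(flip)) elems[flip, ] <- elems[flip, c(1, 2, 4, 3)]

  mesh <- structure(list(nodes = nodes, elems = elems), class = "tet_mesh")
  mesh$node_sets <- list(
    end_min = which(grid$x == xs[1]),
    end_max = which(grid$x == xs[nx + 1]),
    side_ymin = which(grid$y == ys[1]), side_ymax = which(grid$y == ys[ny + 1]),
    side_zmin = which(grid$z == zs[1]), side_zmax = which(grid$z == zs[nz + 1]))
  mesh$face_sets <- lapply(mesh$node_sets, function(set)
    boundary_faces(mesh, set))
  mesh
}

#' Signed volumes of tetrahedra
#' @param nodes n x 3 node coordinates.
#' @param elems m x 4 element connectivity.
#' @return vector of signed volumes.
#' @export
tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 2], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 3], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  d <- nodes[elems[, 4], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
     a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
     a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

# Boundary triangles of the mesh whose three nodes all lie in `node_set`.
boundary_faces <- function(mesh, node_set) {
  el <- mesh$elems
  tri <- rbind(el[, c(1, 3, 2)], el[, c(1, 2, 4)],
               el[, c(1, 4, 3)], el[, c(2, 3, 4)])
  srt <- cbind(pmin(tri[, 1], tri[, 2], tri[, 3]),
               pmax(tri[, 1], tri[, 2], tri[, 3]))
  mid <- tri[, 1] + tri[, 2] + tri[, 3] - srt[, 1] - srt[, 2]
  key <- paste(srt[, 1], mid, srt[, 2])
  counts <- table(key)
  bnd <- tri[key %in% names(counts)[counts == 1], , drop = FALSE]
  keep <- matrix(bnd %in% node_set, ncol = 3)
  bnd[rowSums(keep) == 3, , drop = FALSE]
}

#' Areas of triangular faces
#' @param nodes n x 3 coordinates.
#' @param faces f x 3 node indices.
#' @return vector of face areas.
#' @export
face_areas <- function(nodes, faces) {
  faces <- rbind(faces)
  a <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  b <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Synthetic curved-beam coracoid mesh in the anatomical frame
#'
#' A coracoid-like solid for FEA: a slender beam running medially from the
#' glenoid, tilted posteriorly and bowed in the x-z plane, with the
#' anatomically named node/face sets the loading scenarios require:
#' `medial_surface` (medial end, interface to the epicoracoid cartilage),
#' `glenoid_patch` (lateral end), and `posteromedial_patch` (posterior side
#' near the medial end). Named points give the glenoid center and the
#' anteromedial/posteromedial coracoid tips.
#'
#' @param length,width,height beam dimensions (mm).
#' @param divisions cells per axis, `c(nx, ny, nz)`.
#' @param angle posterior tilt of the long axis (degrees).
#' @param curvature transverse bow as a fraction of length.
#' @param patch_frac fraction of the beam length covered by the
#'   posteromedial patch at the medial end (reported with results).
#' @return a `tet_mesh` with `face_sets$medial_surface`,
#'   `face_sets$glenoid_patch`, `face_sets$posteromedial_patch` and a
#'   `points` matrix.
#' @export
make_coracoid_mesh <- function(length = 7, width = 2.5, height = 1.6,
                               divisions = c(14, 5, 4), angle = 20,
                               curvature = 0.08, patch_frac = 0.2) {
  beam <- make_tet_beam(length, width, height, divisions)
  # beam axis x -> medial; map into the anatomical frame: medially = -x,
  # width (y of beam) -> anteroposterior (z), height -> dorsoventral (y);
  # the bow is a volume-preserving shear toward posterior (-z), growing
  # quadratically toward the medial end
  al <- angle * pi / 180
  raw <- beam$nodes
  nodes <- cbind(-raw[, 1], raw[, 3],
                 raw[, 2] - curvature * raw[, 1]^2 / length)
  Rm <- rot_y(-al)                                     # tilt posteriorly
  nodes <- nodes %*% t(Rm)
  beam$nodes <- nodes

  n <- nrow(nodes)
  xs_raw <- raw[, 1]
  med_cut <- (1 - patch_frac) * length
  post_nodes <- which(abs(raw[, 2] - (-width / 2)) < 1e-9 & xs_raw >= med_cut)
  beam$face_sets <- list(
    medial_surface = beam$face_sets$end_max,
    glenoid_patch = beam$face_sets$end_min,
    posteromedial_patch = boundary_faces(beam, post_nodes))
  beam$node_sets <- list(
    medial_surface = beam$node_sets$end_max,
    glenoid_patch = beam$node_sets$end_min,
    posteromedial_patch = post_nodes)
  glen <- colMeans(nodes[beam$node_sets$glenoid_patch, , drop = FALSE])
  med <- colMeans(nodes[beam$node_sets$medial_surface, , drop = FALSE])
  axis_dir <- unit_vec(med - glen)
  perp <- unit_vec(cross3(c(0, 1, 0), axis_dir))
  beam$points <- rbind(glenoid_center = glen,
                       coracoid_anteromedial_tip = med + perp * width / 2,
                       posteromedial_coracoid_tip = med - perp * width / 2)
  beam$patch_frac <- patch_frac
  beam
}
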