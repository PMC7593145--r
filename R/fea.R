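# Linear-elastic finite-element analysis with 4-node (constant-strain)
# tetrahedra. Voigt order: (xx, yy, zz, xy, yz, zx) with engineering shear
# strains. Units: nodes in mm, E in Pa -> stresses in Pa when forces are in
# uN-equivalents; the package keeps E in Pa and forces in N with nodes in
# mm, so stresses come out in N/mm^2 = MPa times 1e6 ... to avoid unit
# surprises everything is computed consistently in (N, mm): E is taken in
# Pa and converted to N/mm^2 (MPa) internally; reported stresses are Pa.

iso_elastic_D <- function(E, nu) {
  stop_if(E <= 0, "Young's modulus must be positive")
  stop_if(nu < 0 || nu >= 0.5, "Poisson ratio must be in [0, 0.5)")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# B matrix (6 x 12) and volume of one linear tet.
tet_B <- function(x) {
  J <- rbind(x[2, ] - x[1, ], x[3, ] - x[1, ], x[4, ] - x[1, ])
  detJ <- det(J)
  V <- detJ / 6
  grads_local <- rbind(c(-1, -1, -1), diag(3))      # dN/dxi
  grads <- grads_local %*% t(solve(J))               # dN/dx, 4 x 3
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    g <- grads[a, ]
    B[1, c0 + 1] <- g[1]; B[2, c0 + 2] <- g[2]; B[3, c0 + 3] <- g[3]
    B[4, c0 + 1] <- g[2]; B[4, c0 + 2] <- g[1]
    B[5, c0 + 2] <- g[3]; B[5, c0 + 3] <- g[2]
    B[6, c0 + 1] <- g[3]; B[6, c0 + 3] <- g[1]
  }
  list(B = B, V = V)
}

tet_aspect_ratios <- function(nodes, elems) {
  edge_pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  emax <- rep(0, nrow(elems))
  for (r in seq_len(6)) {
    d <- nodes[elems[, edge_pairs[r, 1]], , drop = FALSE] -
      nodes[elems[, edge_pairs[r, 2]], , drop = FALSE]
    emax <- pmax(emax, sqrt(rowSums(d^2)))
  }
  V <- abs(tet_volumes(nodes, elems))
  amax <- rep(0, nrow(elems))
  face_local <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (r in seq_len(4))
    amax <- pmax(amax, face_areas(nodes, elems[, face_local[r, ], drop = FALSE]))
  emax / (3 * V / amax)          # longest edge over shortest altitude
}

#' Assemble and solve a linear-elastic tetrahedral model
#'
#' Constant-strain tetrahedron formulation: element stiffness
#' `Ke = V * B' D B`, sparse global assembly, Dirichlet constraints by
#' elimination (free/fixed DOF partition; nonzero prescribed values
#' supported), symmetric sparse solve. The relative residual
#' `||K u - f|| / ||f||` and the reaction forces at constrained DOFs are
#' reported.
#'
#' @param mesh a `tet_mesh` (`nodes` in mm, `elems` m x 4).
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio.
#' @param loads n x 3 matrix of nodal forces (N), or `NULL`.
#' @param fixed_nodes node indices fully fixed (all three components), or
#'   `NULL` when `fixed_dofs` is given directly.
#' @param fixed_dofs integer vector of constrained global DOFs
#'   (`3*(node-1)+component`); overrides/extends `fixed_nodes`.
#' @param fixed_values prescribed displacements for `fixed_dofs`
#'   (default 0; mm).
#' @param max_aspect element-quality gate: meshes containing a tet with
#'   aspect ratio (longest edge / shortest altitude) above this are
#'   rejected.
#' @return an `fea_result`: `u` (n x 3 displacements, mm), `reactions`
#'   (forces at constrained DOFs, N), `residual` (relative), per-element
#'   `stress` (6 x m, Pa), `von_mises` (Pa), `volumes` (mm^3), `mwam` (Pa).
#' @export
fea_solve <- function(mesh, E = 10e9, nu = 0.35, loads = NULL,
                      fixed_nodes = NULL, fixed_dofs = NULL,
                      fixed_values = NULL, max_aspect = 50) {
  nodes <- mesh$nodes; elems <- mesh$elems
  n <- nrow(nodes); m <- nrow(elems)
  ar <- tet_aspect_ratios(nodes, elems)
  stop_if(any(ar > max_aspect),
          "mesh rejected: tet aspect ratio ", format(max(ar), digits = 4),
          " exceeds the quality gate (", max_aspect, ")")
  E_mm <- E * 1e-6                       # Pa -> N/mm^2
  D <- iso_elastic_D(E_mm, nu)

  # vectorized element kinematics: per-element shape-function gradients from
  # closed-form cross products (element index runs down the rows)
  x1 <- nodes[elems[, 1], , drop = FALSE]
  a <- nodes[elems[, 2], , drop = FALSE] - x1
  b <- nodes[elems[, 3], , drop = FALSE] - x1
  cc <- nodes[elems[, 4], , drop = FALSE] - x1
  rowcross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                   u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                   u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- rowcross(b, cc)
  detJ <- rowSums(a * bxc)
  Vs <- detJ / 6
  g2 <- bxc / detJ
  g3 <- rowcross(cc, a) / detJ
  g4 <- rowcross(a, b) / detJ
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)            # each m x 3

  # B as a 6 x 12 x m sparse pattern: column 3(a-1)+d holds the strain
  # contributions of node a, displacement component d
  Bcol <- function(aa, d) {
    g <- grads[[aa]]
    out <- matrix(0, m, 6)
    out[, d] <- g[, d]                                     # normal strain
    sh <- switch(d, c(4, 6), c(4, 5), c(5, 6))             # xy/zx, xy/yz, yz/zx
    oth <- switch(d, c(2, 3), c(1, 3), c(2, 1))
    out[, sh[1]] <- g[, oth[1]]
    out[, sh[2]] <- g[, oth[2]]
    out
  }
  Bcols <- vector("list", 12)
  for (aa in 1:4) for (d in 1:3) Bcols[[3 * (aa - 1) + d]] <- Bcol(aa, d)

  # Ke[p, q] = V * B[, p]' D B[, q], vectorized over elements
  DB <- lapply(Bcols, function(Bc) Bc %*% D)   # m x 6 each (D symmetric)
  dof_mat <- matrix(0L, m, 12)
  for (aa in 1:4) for (d in 1:3)
    dof_mat[, 3 * (aa - 1) + d] <- 3L * (elems[, aa] - 1L) + d
  idx_i <- integer(144 * m); idx_j <- integer(144 * m); vals <- numeric(144 * m)
  pos <- 0L
  for (p in 1:12) for (q in 1:12) {
    sl <- pos + seq_len(m)
    idx_i[sl] <- dof_mat[, p]
    idx_j[sl] <- dof_mat[, q]
    vals[sl] <- Vs * rowSums(DB[[p]] * Bcols[[q]])
    pos <- pos + m
  }
  K <- Matrix::sparseMatrix(i = idx_i, j = idx_j, x = vals,
                            dims = c(3 * n, 3 * n))

  f <- numeric(3 * n)
  if (!is.null(loads)) {
    stop_if(nrow(loads) != n, "loads must be an n x 3 nodal force matrix")
    f <- as.vector(t(loads))
  }
  fixed <- integer(0); uvals <- numeric(0)
  if (!is.null(fixed_nodes)) {
    fixed <- as.vector(t(outer(fixed_nodes, 1:3, function(nd, c) 3 * (nd - 1) + c)))
    uvals <- rep(0, length(fixed))
  }
  if (!is.null(fixed_dofs)) {
    fixed <- c(fixed, fixed_dofs)
    uvals <- c(uvals, fixed_values %||% rep(0, length(fixed_dofs)))
  }
  dup <- !duplicated(fixed)
  fixed <- fixed[dup]; uvals <- uvals[dup]
  stop_if(length(fixed) < 1, "no constraints: all six rigid-body modes are free")
  free <- setdiff(seq_len(3 * n), fixed)

  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  rhs <- f[free] - as.vector(K[free, fixed, drop = FALSE] %*% uvals)
  u_free <- tryCatch({
    ch <- Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE)
    as.vector(Matrix::solve(ch, rhs))
  }, error = function(e) stop("singular stiffness system (insufficient ",
                              "constraints leave rigid-body modes free): ",
                              conditionMessage(e), call. = FALSE))
  u <- numeric(3 * n)
  u[free] <- u_free; u[fixed] <- uvals

  Ku <- as.vector(K %*% u)
  resid_rel <- sqrt(sum((Ku[free] - f[free])^2)) / max(sqrt(sum(f[free]^2)), 1e-300)
  reactions <- Ku[fixed] - f[fixed]

  eps <- matrix(0, m, 6)
  for (p in 1:12) eps <- eps + Bcols[[p]] * u[dof_mat[, p]]
  stress_pa <- t(eps %*% D) * 1e6          # N/mm^2 -> Pa, 6 x m
  svm <- von_mises_stress(stress_pa)

  structure(list(u = matrix(u, n, 3, byrow = TRUE), reactions = reactions,
                 fixed_dofs = fixed, residual = resid_rel,
                 stress = stress_pa, von_mises = svm, volumes = Vs,
                 mwam = mwam(svm, Vs)),
            class = "fea_result")
}

#' Von Mises stress from Voigt stress vectors
#' @param stress 6 x m matrix in Voigt order (xx, yy, zz, xy, yz, zx), Pa.
#' @return vector of von Mises stresses (Pa).
#' @export
von_mises_stress <- function(stress) {
  s <- stress
  sqrt(0.5 * ((s[1, ] - s[2, ])^2 + (s[2, ] - s[3, ])^2 + (s[3, ] - s[1, ])^2) +
         3 * (s[4, ]^2 + s[5, ]^2 + s[6, ]^2))
}

#' Mesh-weighted arithmetic mean von Mises stress
#'
#' Element von Mises stresses averaged with element-volume weights, making
#' mean stress comparable across meshes of different refinement.
#'
#' @param sigma_vm per-element von Mises stresses (Pa).
#' @param volumes per-element volumes (mm^3), all positive.
#' @return mwam (Pa).
#' @export
mwam <- function(sigma_vm, volumes) {
  stop_if(length(sigma_vm) == 0, "empty element list")
  stop_if(length(volumes) != length(sigma_vm), "lengths differ")
  stop_if(any(volumes <= 0), "element volumes must be positive")
  sum(sigma_vm * volumes) / sum(volumes)
}

#' @export
print.fea_result <- function(x, ...) {
  cat(sprintf("fea_result: %d elements, residual %.2e\n", length(x$von_mises),
              x$residual))
  cat(sprintf("  von Mises stress: min %.4g, mwam %.4g, max %.4g Pa\n",
              min(x$von_mises), x$mwam, max(x$von_mises)))
  invisible(x)
}

#' Build a loading scenario for a coracoid model
#'
#' Encodes the five loading scenarios: I and II fix the medial surface and
#' load a part of the glenoidal surface (I compressively along the coracoid
#' long axis, the line from the mean of the anteromedial and posteromedial
#' coracoid tips to the shoulder-joint center; II compressively along -x,
#' perpendicular to the sagittal plane); III-V fix the glenoid patch and
#' load the posteromedial patch (III in tension along the posterior
#' muscle's reference-pose line, IV anteriorly along +z, V posteriorly
#' along -z). The total load is distributed over the loaded faces in
#' proportion to face area (each face's share split equally among its three
#' nodes), so the applied nodal forces sum exactly to `F_total` times the
#' unit direction.
#'
#' @param mesh a `tet_mesh` with face sets `medial_surface`,
#'   `glenoid_patch`, `posteromedial_patch` and a `points` matrix carrying
#'   the coracoid tips and glenoid center (e.g. [make_coracoid_mesh()]).
#' @param scenario `"I"` through `"V"`.
#' @param F_total total applied force (N).
#' @param muscle_model optional `muscle_model` providing the posterior
#'   muscle line for scenario III; defaults to the line from the
#'   posteromedial patch toward the glenoid-level insertion point used by
#'   [build_default_muscles()].
#' @return a `load_case`: `fixed_nodes`, `loads` (n x 3), unit `direction`,
#'   `scenario`, `F_total`.
#' @export
build_scenario <- function(mesh, scenario = c("I", "II", "III", "IV", "V"),
                           F_total = 1, muscle_model = NULL) {
  scenario <- match.arg(scenario)
  need <- c("medial_surface", "glenoid_patch", "posteromedial_patch")
  stop_if(!all(need %in% names(mesh$face_sets)),
          "mesh must provide face sets: ", paste(need, collapse = ", "))
  pts <- mesh$points
  stop_if(is.null(pts), "mesh must carry named points (coracoid tips, glenoid)")

  glen <- pts["glenoid_center", ]
  tip_mean <- (pts["coracoid_anteromedial_tip", ] +
                 pts["posteromedial_coracoid_tip", ]) / 2
  long_axis <- unit_vec(glen - tip_mean)      # medial tips -> joint center

  if (scenario %in% c("I", "II")) {
    fixed_set <- "medial_surface"; load_set <- "glenoid_patch"
    direction <- if (scenario == "I") -long_axis else c(-1, 0, 0)
  } else {
    fixed_set <- "glenoid_patch"; load_set <- "posteromedial_patch"
    direction <- switch(scenario,
      III = {
        origin <- pts["posteromedial_coracoid_tip", ]
        insertion <- if (!is.null(muscle_model)) {
          m <- muscle_model$muscles$posterior
          stop_if(is.null(m), "muscle model lacks a posterior muscle")
          drop(pose_rotation(0, 0) %*% m$insertion_local)
        } else c(2, 0, 0)
        unit_vec(insertion - origin)
      },
      IV = c(0, 0, 1),
      V = c(0, 0, -1))
  }
  direction <- unit_vec(direction)

  faces <- mesh$face_sets[[load_set]]
  areas <- face_areas(mesh$nodes, faces)
  loads <- matrix(0, nrow(mesh$nodes), 3)
  for (i in seq_len(nrow(faces))) {
    fshare <- F_total * areas[i] / sum(areas) / 3
    for (nd in faces[i, ]) loads[nd, ] <- loads[nd, ] + fshare * direction
  }
  fixed_nodes <- mesh$node_sets[[fixed_set]]
  stop_if(length(intersect(fixed_nodes, unique(as.vector(faces)))) > 0,
          "fixed and loaded sets overlap")
  structure(list(scenario = scenario, fixed_nodes = fixed_nodes,
                 load_set = load_set, loads = loads, direction = direction,
                 F_total = F_total),
            class = "load_case")
}

#' Run the five loading scenarios on a coracoid mesh
#'
#' @param mesh a coracoid-like `tet_mesh` (see [build_scenario()]).
#' @param scenarios subset of `c("I","II","III","IV","V")`.
#' @param E,nu material parameters (Pa, dimensionless).
#' @param F_total total force per scenario (N); equal across scenarios.
#' @param muscle_model optional, for scenario III.
#' @return data frame with scenario, mwam (Pa), max von Mises (Pa),
#'   residual.
#' @export
run_fea_scenarios <- function(mesh, scenarios = c("I", "II", "III", "IV", "V"),
                              E = 10e9, nu = 0.35, F_total = 1,
                              muscle_model = NULL) {
  rows <- lapply(scenarios, function(sc) {
    lc <- build_scenario(mesh, sc, F_total = F_total,
                         muscle_model = muscle_model)
    res <- fea_solve(mesh, E = E, nu = nu, loads = lc$loads,
                     fixed_nodes = lc$fixed_nodes)
    data.frame(scenario = sc, mwam_pa = res$mwam,
               max_vm_pa = max(res$von_mises), residual = res$residual)
  })
  do.call(rbind, rows)
}
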