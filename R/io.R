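# Plain-text interchange formats: TPS landmark files, the landmark CSV
# dialect, surface meshes (OFF/PLY/STL ASCII), tetrahedral meshes (Gmsh MSH
# v2 ASCII, legacy VTK), TIFF stacks / raw volumes, and JSON reports.

#' Write landmark configurations to a TPS file
#'
#' Standard TPS layout: one `LM3=` block per configuration with an `ID=`
#' line; centroid size is stored as `CSIZE=` when available.
#'
#' @param configs list of `landmark_config` objects.
#' @param path output file.
#' @param ids configuration identifiers (default `names(configs)` or
#'   running numbers).
#' @export
write_tps <- function(configs, path, ids = NULL) {
  ids <- ids %||% names(configs) %||% as.character(seq_along(configs))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(configs)) {
    cc <- configs[[i]]
    writeLines(sprintf("LM3=%d", nrow(cc$coords)), con)
    utils::write.table(format(cc$coords, trim = TRUE, digits = 12), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    writeLines(sprintf("ID=%s", ids[i]), con)
    if (!any(cc$missing))
      writeLines(sprintf("CSIZE=%.10g", centroid_size(cc)), con)
  }
  invisible(path)
}

#' Read a TPS landmark file
#' @param path TPS file written by [write_tps()] (LM3 blocks).
#' @param scheme optional `landmark_config` providing curves/bones to attach.
#' @return named list of `landmark_config` objects.
#' @export
read_tps <- function(path, scheme = NULL) {
  lines <- readLines(path)
  out <- list(); i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^LM3=", ln)) {
      k <- as.integer(sub("^LM3=", "", ln))
      coords <- do.call(rbind, lapply(lines[i + seq_len(k)], function(s)
        as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
      i <- i + k + 1
      id <- as.character(length(out) + 1)
      while (i <= length(lines) && grepl("^(ID|CSIZE)=", lines[i])) {
        if (grepl("^ID=", lines[i])) id <- sub("^ID=", "", lines[i])
        i <- i + 1
      }
      cc <- if (is.null(scheme))
        landmark_config(coords)
      else landmark_config(coords, curves = scheme$curves, bone = scheme$bone,
                           side = scheme$side, labels = rownames(scheme$coords))
      out[[id]] <- cc
    } else i <- i + 1
  }
  out
}

#' Write landmark configurations as a long-format CSV
#'
#' Columns: specimen, species, landmark, x, y, z, curve, bone.
#'
#' @param configs list of `landmark_config`.
#' @param path output file.
#' @param specimen,species character vectors (recycled) labelling each
#'   configuration.
#' @export
write_landmark_csv <- function(configs, path, specimen = NULL, species = NULL) {
  specimen <- rep_len(specimen %||% names(configs) %||%
                        as.character(seq_along(configs)), length(configs))
  species <- rep_len(species %||% specimen, length(configs))
  rows <- lapply(seq_along(configs), function(i) {
    cc <- configs[[i]]
    curve_of <- rep(NA_character_, nrow(cc$coords))
    for (nm in names(cc$curves)) curve_of[cc$curves[[nm]]] <- nm
    data.frame(specimen = specimen[i], species = species[i],
               landmark = rownames(cc$coords),
               x = cc$coords[, 1], y = cc$coords[, 2], z = cc$coords[, 3],
               curve = curve_of, bone = cc$bone)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read the landmark CSV written by [write_landmark_csv()]
#' @param path CSV file.
#' @param scheme optional `landmark_config` supplying the curve scheme.
#' @return list of `landmark_config` with attributes preserved per specimen.
#' @export
read_landmark_csv <- function(path, scheme = NULL) {
  df <- utils::read.csv(path)
  out <- list()
  for (sp in unique(df$specimen)) {
    sub <- df[df$specimen == sp, ]
    coords <- as.matrix(sub[, c("x", "y", "z")])
    rownames(coords) <- sub$landmark
    out[[as.character(sp)]] <- if (is.null(scheme))
      landmark_config(coords, bone = sub$bone)
    else landmark_config(coords, curves = scheme$curves, bone = scheme$bone,
                         side = scheme$side)
  }
  out
}

#' Write a triangle mesh (OFF, PLY or STL ASCII)
#' @param mesh a `tri_mesh`.
#' @param path output path; format chosen by extension (.off, .ply, .stl).
#' @export
write_surface <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  if (ext == "off") {
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    utils::write.table(format(v, digits = 12, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3, f - 1), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    utils::write.table(format(v, digits = 12, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3, f - 1), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else if (ext == "stl") {
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; d <- v[f[i, 3], ]
      nrm <- cross3(b - a, d - a)
      nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
      writeLines(c(sprintf("facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                   "  outer loop",
                   sprintf("    vertex %g %g %g", a[1], a[2], a[3]),
                   sprintf("    vertex %g %g %g", b[1], b[2], b[3]),
                   sprintf("    vertex %g %g %g", d[1], d[2], d[3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else stop("unsupported surface format: .", ext, call. = FALSE)
  invisible(path)
}

#' Read an OFF triangle mesh
#' @param path OFF file.
#' @return a `tri_mesh`.
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  stop_if(trimws(lines[1]) != "OFF", "not an OFF file")
  hdr <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  v <- do.call(rbind, lapply(lines[2 + seq_len(nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  f <- do.call(rbind, lapply(lines[2 + nv + seq_len(nf)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]])[2:4] + 1L))
  structure(list(vertices = v, faces = f), class = "tri_mesh")
}

#' Write a tetrahedral mesh as Gmsh MSH v2 ASCII
#' @param mesh a `tet_mesh`.
#' @param path output file.
#' @export
write_msh2 <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.12g %.12g %.12g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$elems))), con)
  writeLines(sprintf("%d 4 2 0 1 %d %d %d %d", seq_len(nrow(mesh$elems)),
                     mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3],
                     mesh$elems[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH v2 ASCII tetrahedral mesh
#' @param path MSH file.
#' @return a `tet_mesh` (node/face sets not stored by the format).
#' @export
read_msh2 <- function(path) {
  lines <- readLines(path)
  ni <- which(lines == "$Nodes"); ei <- which(lines == "$Elements")
  nn <- as.integer(lines[ni + 1])
  nodes <- do.call(rbind, lapply(lines[ni + 1 + seq_len(nn)], function(s)
    as.numeric(strsplit(s, "\\s+")[[1]])[2:4]))
  ne <- as.integer(lines[ei + 1])
  el <- do.call(rbind, lapply(lines[ei + 1 + seq_len(ne)], function(s) {
    v <- as.integer(strsplit(s, "\\s+")[[1]])
    ntags <- v[3]
    utils::tail(v, length(v) - 3 - ntags)
  }))
  structure(list(nodes = nodes, elems = el), class = "tet_mesh")
}

#' Write a tetrahedral mesh (optionally with cell data) as legacy VTK
#' @param mesh a `tet_mesh`.
#' @param path output file.
#' @param cell_data optional named list of per-element numeric vectors
#'   (e.g. von Mises stress) stored as CELL_DATA scalars.
#' @export
write_vtk <- function(mesh, path, cell_data = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 2.0", "girdlemorph mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elems[, 1] - 1, mesh$elems[, 2] - 1,
                     mesh$elems[, 3] - 1, mesh$elems[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (!is.null(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%.12g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Read a legacy VTK unstructured tetrahedral mesh
#' @param path VTK file written by [write_vtk()].
#' @return a `tet_mesh`; cell data (if any) attached as `cell_data`.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  pi_ <- grep("^POINTS", lines)
  n <- as.integer(strsplit(lines[pi_], "\\s+")[[1]][2])
  nodes <- do.call(rbind, lapply(lines[pi_ + seq_len(n)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  ci <- grep("^CELLS", lines)
  m <- as.integer(strsplit(lines[ci], "\\s+")[[1]][2])
  elems <- do.call(rbind, lapply(lines[ci + seq_len(m)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]])[2:5] + 1L))
  mesh <- structure(list(nodes = nodes, elems = elems), class = "tet_mesh")
  di <- grep("^SCALARS", lines)
  if (length(di)) {
    cd <- list()
    for (ii in di) {
      nm <- strsplit(lines[ii], "\\s+")[[1]][2]
      cd[[nm]] <- as.numeric(lines[ii + 1 + seq_len(m)])
    }
    mesh$cell_data <- cd
  }
  mesh
}

#' Write a 3D volume as a multi-page 16-bit TIFF stack
#' @param volume 3D integer/numeric array with values in `[0, 65535]`.
#' @param path output .tif file.
#' @param voxel_size voxel edge length (mm), stored in a JSON sidecar.
#' @export
write_volume_tiff <- function(volume, path, voxel_size = NULL) {
  stop_if(!requireNamespace("tiff", quietly = TRUE),
          "the 'tiff' package is required for TIFF output")
  slices <- lapply(seq_len(dim(volume)[3]), function(s)
    volume[, , s] / 65535)
  tiff::writeTIFF(slices, path, bits.per.sample = 16)
  if (!is.null(voxel_size))
    jsonlite::write_json(list(shape = dim(volume), dtype = "uint16",
                              voxel_size_mm = voxel_size),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF stack as a 3D volume
#' @param path .tif file.
#' @return integer 3D array scaled back to `[0, 65535]`.
#' @export
read_volume_tiff <- function(path) {
  stop_if(!requireNamespace("tiff", quietly = TRUE),
          "the 'tiff' package is required for TIFF input")
  slices <- tiff::readTIFF(path, all = TRUE)
  vol <- array(0L, c(dim(slices[[1]]), length(slices)))
  for (s in seq_along(slices))
    vol[, , s] <- as.integer(round(slices[[s]] * 65535))
  vol
}

#' Write a synthetic sample to disk (landmarks, tree, ground truth)
#'
#' Writes the specimen landmarks as TPS and CSV, the phylogeny as Newick,
#' and the generator's ground truth (directions, deviations, sizes, group
#' assignment) as JSON.
#'
#' @param sample a `synth_sample` from [sim_species_shapes()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_synth_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("%s_%02d", sample$specimen_species,
                 stats::ave(seq_along(sample$specimen_species),
                            sample$specimen_species, FUN = seq_along))
  files <- c(
    write_tps(sample$specimens, file.path(dir, "specimens.tps"), ids = ids),
    write_landmark_csv(sample$specimens, file.path(dir, "specimens.csv"),
                       specimen = ids, species = sample$specimen_species))
  ape::write.tree(sample$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(species = sample$species, group = as.character(sample$group),
         logCS = sample$logCS, clav_absent = sample$clav_absent,
         u_group = sample$truth$u_group, u_allom = sample$truth$u_allom,
         log_size = sample$truth$log_size,
         group_allometry_cos = sample$truth$group_allometry_cos,
         cfg = unclass(sample$cfg)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(files, file.path(dir, c("tree.nwk", "ground_truth.json"))))
}

#' Write a GPA alignment report as JSON
#'
#' Records iterations, convergence, centroid sizes, Procrustes distances
#' and the bending-energy trace of a superimposition.
#'
#' @param fit a `gpa_fit`.
#' @param path output JSON file.
#' @export
write_gpa_report <- function(fit, path) {
  jsonlite::write_json(
    list(n_configs = dim(fit$aligned)[3], n_landmarks = dim(fit$aligned)[1],
         n_iterations = fit$n_iterations, converged = fit$converged,
         centroid_sizes = fit$centroid_sizes,
         procrustes_distances = fit$procrustes_distances,
         bending_energy_trace = fit$bending_energy_trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
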