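# Serialization: PLY surfaces, TSV electrode/projection/voltage tables,
# legacy-VTK unstructured grids, raw recordings with a YAML sidecar, and
# YAML run manifests.

#' Write / read a surface as ASCII PLY
#'
#' @param s a [tri_surface()].
#' @param path file path (.ply).
#' @return `write_surface_ply()`: the path, invisibly; `read_surface_ply()`:
#'   a [tri_surface()] (without analytic metadata).
#' @export
write_surface_ply <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("comment tissue %s", s$name),
    sprintf("element vertex %d", nrow(s$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(s$faces)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  utils::write.table(format(s$vertices, trim = TRUE, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, s$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface_ply
#' @param path file path.
#' @export
read_surface_ply <- function(path) {
  lines <- readLines(path)
  hend <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  nm <- sub("comment tissue ", "", grep("^comment tissue", lines, value = TRUE))
  if (!length(nm)) nm <- "surface"
  v <- do.call(rbind, lapply(strsplit(lines[hend + seq_len(nv)], " +"), as.numeric))
  f <- do.call(rbind, lapply(strsplit(lines[hend + nv + seq_len(nf)], " +"), as.integer))
  tri_surface(v, f[, 2:4] + 1L, name = nm)
}

#' Write an electrode table as TSV
#'
#' Columns: label, x, y, z (rigid centroid, mm), row, col.
#'
#' @param electrodes an [electrode_set()].
#' @param path file path (.tsv).
#' @export
write_electrodes_tsv <- function(electrodes, path) {
  c_ <- electrodes$grid_shape[2]
  k <- seq_along(electrodes$labels)
  df <- data.frame(
    label = electrodes$labels,
    x = electrodes$rigid_centroids[, 1],
    y = electrodes$rigid_centroids[, 2],
    z = electrodes$rigid_centroids[, 3],
    row = (k - 1L) %/% c_ + 1L,
    col = (k - 1L) %% c_ + 1L
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a projection result as TSV plus a YAML run manifest
#'
#' TSV columns: label, x, y, z, dx, dy, dz, distance_mm, method, converged.
#'
#' @param result a [projection_result()].
#' @param path TSV path; the manifest is written next to it as
#'   `<path>.manifest.yaml`.
#' @param csf_depth_mm,seed,tol_mm metadata recorded in the manifest.
#' @export
write_projection_tsv <- function(result, path, csf_depth_mm = 0, seed = NA,
                                 tol_mm = NA) {
  df <- data.frame(
    label = result$labels,
    x = result$projected_centroids[, 1],
    y = result$projected_centroids[, 2],
    z = result$projected_centroids[, 3],
    dx = result$projection_vectors[, 1],
    dy = result$projection_vectors[, 2],
    dz = result$projection_vectors[, 3],
    distance_mm = result$projection_distances,
    method = result$method,
    converged = result$converged
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(method = result$method, csf_depth_mm = csf_depth_mm,
         iterations = result$iterations, converged = result$converged,
         tol_mm = tol_mm, seed = seed),
    paste0(path, ".manifest.yaml")
  )
  invisible(path)
}

#' Write per-electrode voltages as TSV
#'
#' @param voltages named voltage vector (volts).
#' @param path file path.
#' @param column value column name (default `V_sim_volts`).
#' @export
write_voltages_tsv <- function(voltages, path, column = "V_sim_volts") {
  df <- data.frame(label = names(voltages), v = unname(voltages))
  names(df)[2] <- column
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a tetrahedral mesh as legacy ASCII VTK
#'
#' Unstructured-grid layout with a per-cell region tag.
#'
#' @param mesh a [tet_mesh()].
#' @param path file path (.vtk).
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, trim = TRUE, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  regions <- factor(mesh$region)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(regions) - 1L), con)
  writeLines(paste("# region levels:", paste(levels(regions), collapse = " ")),
             con)
  invisible(path)
}

#' Write / read a pulse recording
#'
#' Samples as a raw little-endian double array (channels fastest) with a
#' YAML sidecar holding the sampling rate, onsets, amplitude and labels.
#'
#' @param recording a [pulse_recording()].
#' @param stem path stem; writes `<stem>.f64` and `<stem>.yaml`.
#' @export
write_recording <- function(recording, stem) {
  con <- file(paste0(stem, ".f64"), "wb")
  writeBin(as.vector(recording$samples), con, size = 8, endian = "little")
  close(con)
  yaml::write_yaml(
    list(n_channels = nrow(recording$samples),
         n_samples = ncol(recording$samples),
         channels = rownames(recording$samples),
         sampling_rate = recording$sampling_rate,
         pulse_onsets = recording$pulse_onsets,
         stim_amplitude_mA = recording$stim_amplitude_mA,
         phase_width_ms = recording$phase_width_ms,
         stim_pair = recording$stim_pair),
    paste0(stem, ".yaml")
  )
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  meta <- yaml::read_yaml(paste0(stem, ".yaml"))
  con <- file(paste0(stem, ".f64"), "rb")
  x <- readBin(con, "double", n = meta$n_channels * meta$n_samples, size = 8,
               endian = "little")
  close(con)
  samples <- matrix(x, meta$n_channels, meta$n_samples)
  rownames(samples) <- unlist(meta$channels)
  pulse_recording(samples, meta$sampling_rate, unlist(meta$pulse_onsets),
                  meta$stim_amplitude_mA, meta$phase_width_ms,
                  unlist(meta$stim_pair))
}

#' Write a grid-report summary as TSV + YAML manifest
#'
#' @param report a `grid_report` from [run_grid()].
#' @param dir output directory (created if needed).
#' @export
write_grid_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (m in names(report$depth_comparisons)) {
    utils::write.table(report$depth_comparisons[[m]],
                       file.path(dir, sprintf("depth_comparisons_%s.tsv", m)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  yaml::write_yaml(
    list(conditions = names(report$conditions),
         non_converged = report$non_converged),
    file.path(dir, "manifest.yaml")
  )
  invisible(dir)
}
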