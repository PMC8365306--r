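# Region-labelled tetrahedral meshing on tensor-product grids. Grid planes
# are aligned to the tissue interfaces (gray top, CSF film, silicone sheet),
# every cube is split into six tetrahedra sharing its main diagonal (Kuhn
# subdivision, conforming across cubes), and each tetrahedron is labelled by
# classifying its centroid against the compartment surfaces, innermost
# first. Electrode disks are embedded by P1 barycentric weights, which the
# solver uses both to spread the injected current over the 73 disk nodes
# and to sample the simulated electrode voltage.

#' Tetrahedral mesh with region labels
#'
#' @param nodes n x 3 node coordinates (mm).
#' @param tets m x 4 node indices, positively oriented.
#' @param region character vector (length m) of tissue tags.
#' @param electrode_weights optional sparse matrix (contacts x nodes): each
#'   row averages P1 interpolation weights over a contact's 73 disk nodes
#'   and sums to 1.
#' @param electrode_nodes optional named list of supporting node indices.
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, region, electrode_weights = NULL,
                     electrode_nodes = NULL) {
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4, nrow(tets) == length(region))
  structure(
    list(nodes = nodes, tets = tets, region = region,
         electrode_weights = electrode_weights,
         electrode_nodes = electrode_nodes),
    class = "tet_mesh"
  )
}

#' @export
print.tet_mesh <- function(x, ...) {
  vols <- region_volumes(x)
  cat(sprintf("<tet_mesh: %d nodes, %d tets>\n", nrow(x$nodes), nrow(x$tets)))
  for (nm in names(vols)) cat(sprintf("  %-12s %12.1f mm^3\n", nm, vols[nm]))
  invisible(x)
}

#' Signed tetrahedron volumes
#' @param mesh a [tet_mesh()].
#' @return numeric vector of volumes (mm^3), positive for valid meshes.
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tets
  a <- n[t[, 2], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  b <- n[t[, 3], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  cc <- n[t[, 4], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  row_dot(a, row_cross(b, cc)) / 6
}

#' Per-region mesh volumes
#' @param mesh a [tet_mesh()].
#' @return named numeric vector (mm^3).
#' @export
region_volumes <- function(mesh) {
  v <- tet_volumes(mesh)
  vapply(split(v, mesh$region), sum, numeric(1))
}

# Uniform-then-geometric grid lines: uniform spacing h over `fine`, growing
# by `growth` per step out to `domain`. Endpoints of `fine` are exact.
graded_lines <- function(fine, h, domain = fine, growth = 1.6, h_max = Inf) {
  n <- max(1L, round(diff(fine) / h))
  xs <- seq(fine[1], fine[2], length.out = n + 1)
  left <- numeric(0); x <- fine[1]; step <- h
  while (x > domain[1] + 1e-9) {
    step <- min(step * growth, h_max)
    x <- max(domain[1], x - step)
    left <- c(x, left)
  }
  right <- numeric(0); x <- fine[2]; step <- h
  while (x < domain[2] - 1e-9) {
    step <- min(step * growth, h_max)
    x <- min(domain[2], x + step)
    right <- c(right, x)
  }
  c(left, xs, right)
}

# z grid lines honouring layer interfaces: uniform h_fine within thin upper
# layers, geometric coarsening within deep layers (from the top of each).
layer_lines <- function(breaks, h_fine, growth = 1.6, h_max = 8) {
  breaks <- sort(unique(breaks))
  out <- breaks[1]
  for (i in seq_len(length(breaks) - 1)) {
    z0 <- breaks[i]; z1 <- breaks[i + 1]
    thick <- z1 - z0
    if (thick <= 3 * h_fine + 1e-9) {
      n <- max(1L, round(thick / h_fine))
      zs <- seq(z0, z1, length.out = n + 1)
    } else {
      zs <- z1; step <- h_fine; z <- z1
      while (z > z0 + 1e-9) {
        z <- max(z0, z - step)
        zs <- c(z, zs)
        step <- min(step * growth, h_max)
      }
    }
    out <- c(out, zs[-1])
  }
  out
}

# Kuhn subdivision of a tensor grid: nodes plus 6 positively oriented tets
# per cube. Returns a full-grid mesh; region filtering happens later.
tensor_tet_mesh <- function(xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nodes <- cbind(rep(xs, times = ny * nz),
                 rep(rep(ys, each = nx), times = nz),
                 rep(zs, each = nx * ny))
  nid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  v <- function(dx, dy, dz) nid(ci + dx, cj + dy, ck + dz)
  c000 <- v(0L, 0L, 0L); c100 <- v(1L, 0L, 0L); c010 <- v(0L, 1L, 0L)
  c110 <- v(1L, 1L, 0L); c001 <- v(0L, 0L, 1L); c101 <- v(1L, 0L, 1L)
  c011 <- v(0L, 1L, 1L); c111 <- v(1L, 1L, 1L)
  tets <- rbind(
    cbind(c000, c100, c110, c111),
    cbind(c000, c100, c101, c111),
    cbind(c000, c010, c110, c111),
    cbind(c000, c010, c011, c111),
    cbind(c000, c001, c101, c111),
    cbind(c000, c001, c011, c111)
  )
  # fix orientation (half the Kuhn permutations are left-handed)
  m <- tet_mesh(nodes, tets, rep("x", nrow(tets)))
  vol <- tet_volumes(m)
  flip <- vol < 0
  tets[flip, 3:4] <- tets[flip, 4:3]
  list(nodes = nodes, tets = tets, xs = xs, ys = ys, zs = zs,
       ncubes = length(c000))
}

# Innermost-first centroid classification against an ordered compartment
# list (names = region tags).
classify_points <- function(pts, compartments) {
  region <- rep(NA_character_, nrow(pts))
  for (nm in names(compartments)) {
    todo <- is.na(region)
    if (!any(todo)) break
    inside <- surface_contains(compartments[[nm]], pts[todo, , drop = FALSE])
    region[todo][inside] <- nm
  }
  region
}

# Barycentric coordinates of point p in tet (rows of V); NULL if outside.
tet_barycentric <- function(p, V) {
  M <- cbind(V[2, ] - V[1, ], V[3, ] - V[1, ], V[4, ] - V[1, ])
  b <- tryCatch(solve(M, p - V[1, ]), error = function(e) NULL)
  if (is.null(b)) return(NULL)
  l <- c(1 - sum(b), b)
  if (all(l >= -1e-8)) pmax(l, 0) else NULL
}

#' Region-labelled tetrahedral mesh of a head phantom
#'
#' Builds a tensor-product tetrahedral mesh whose grid planes follow the
#' phantom's layer interfaces, labels tetrahedra by compartment (innermost
#' surface first; unclaimed cells are outside the head and dropped), and
#' embeds the electrode disks as barycentric node-weight sets.
#'
#' @param geometry a [head_geometry()] of slab-type surfaces (and/or
#'   voxel-grid surfaces from clipping).
#' @param sheet optional silicone sheet surface from [build_sheet()];
#'   labelled region `"silicone"`.
#' @param disks optional list of [build_disk()] objects to embed.
#' @param sizing list: `h_fine` (mm, edge length near the electrodes),
#'   `h_coarse` (mm, far field), `fine_xy` (2 x 2 matrix rbind(xlim, ylim)
#'   of the fine region; defaults to the disk footprint + 10 mm),
#'   `growth` (geometric grading ratio).
#' @param csf optional CSF film surface (region `"csf"`, between
#'   closed-gray and the sheet).
#' @param compartments optional explicit ordered list of region surfaces,
#'   overriding the default (white < gray < csf < silicone).
#' @return a [tet_mesh()].
#' @export
tetrahedralize <- function(geometry, sheet = NULL, disks = NULL,
                           sizing = list(), csf = NULL, compartments = NULL) {
  h_fine <- sizing$h_fine %||% 2
  h_coarse <- sizing$h_coarse %||% 8
  growth <- sizing$growth %||% 1.6
  if (is.null(compartments)) {
    compartments <- list()
    ss <- geometry$surfaces
    if (!is.null(ss$white)) compartments$white <- ss$white
    if (!is.null(ss$gray)) compartments$gray <- ss$gray
    else if (!is.null(ss$closed_gray)) compartments$gray <- ss$closed_gray
    if (!is.null(csf)) compartments$csf <- csf
    if (!is.null(sheet)) compartments$silicone <- sheet
  }
  # domain bounds and interface planes from analytic descriptions
  zbreaks <- c(); xbreaks <- c(); ybreaks <- c()
  xacc <- c(); yacc <- c(); zacc <- c()
  for (s in compartments) {
    a <- s$analytic
    vz <- range(s$vertices[, 3])
    if (!is.null(a) && a$type == "slab") {
      zbreaks <- c(zbreaks, a$zlim)
      xbreaks <- c(xbreaks, a$xlim)
      ybreaks <- c(ybreaks, a$ylim)
    } else zbreaks <- c(zbreaks, vz)
    xacc <- range(c(xacc, s$vertices[, 1]))
    yacc <- range(c(yacc, s$vertices[, 2]))
    zacc <- range(c(zacc, vz))
  }
  xlim <- xacc; ylim <- yacc; zlim <- zacc
  zbreaks <- sort(unique(round(c(zbreaks, zlim), 9)))
  fine_xy <- sizing$fine_xy
  if (is.null(fine_xy)) {
    fine_xy <- if (!is.null(disks)) {
      ctrs <- do.call(rbind, lapply(disks, function(d) d$center))
      rbind(range(ctrs[, 1]) + c(-10, 10), range(ctrs[, 2]) + c(-10, 10))
    } else rbind(xlim, ylim)
  }
  fx <- c(max(fine_xy[1, 1], xlim[1]), min(fine_xy[1, 2], xlim[2]))
  fy <- c(max(fine_xy[2, 1], ylim[1]), min(fine_xy[2, 2], ylim[2]))
  xs <- graded_lines(fx, h_fine, xlim, growth, h_coarse)
  ys <- graded_lines(fy, h_fine, ylim, growth, h_coarse)
  # snap grid lines onto lateral compartment boundaries so thin regions
  # (sheet, CSF film) are resolved exactly
  snap_lines <- function(ls, breaks, lim) {
    for (b in breaks) {
      if (b <= lim[1] + 1e-9 || b >= lim[2] - 1e-9) next
      j <- which.min(abs(ls - b))
      if (abs(ls[j] - b) > 1e-9 && j > 1 && j < length(ls)) ls[j] <- b
    }
    sort(unique(ls))
  }
  xs <- snap_lines(xs, xbreaks, xlim)
  ys <- snap_lines(ys, ybreaks, ylim)
  if (!is.null(sizing$z_breaks))
    zbreaks <- sort(unique(c(zbreaks, sizing$z_breaks)))
  zs <- layer_lines(zbreaks, h_fine, growth, h_coarse)
  tm <- tensor_tet_mesh(xs, ys, zs)
  cen <- (tm$nodes[tm$tets[, 1], , drop = FALSE] +
            tm$nodes[tm$tets[, 2], , drop = FALSE] +
            tm$nodes[tm$tets[, 3], , drop = FALSE] +
            tm$nodes[tm$tets[, 4], , drop = FALSE]) / 4
  region <- classify_points(cen, compartments)
  keep <- !is.na(region)
  if (!any(keep)) stop("meshing error: no tetrahedra inside any compartment",
                       call. = FALSE)
  tets <- tm$tets[keep, , drop = FALSE]
  region <- region[keep]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(tm$nodes))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4)
  nodes <- tm$nodes[used, , drop = FALSE]
  mesh <- tet_mesh(nodes, tets, region)
  keep_idx <- which(keep)
  full2kept <- integer(length(keep))
  full2kept[keep_idx] <- seq_along(keep_idx)
  mesh$grid <- list(xs = xs, ys = ys, zs = zs, keep = keep,
                    full2kept = full2kept, ncubes = tm$ncubes)
  if (!is.null(disks)) mesh <- embed_electrodes(mesh, disks)
  mesh
}

#' Embed electrode disks into a structured mesh
#'
#' Locates each of a disk's 73 nodes (nudged slightly into the tissue along
#' the inward normal), computes P1 barycentric weights in the containing
#' tetrahedron, and averages over the disk. The resulting weight rows both
#' spread injected current and sample the simulated voltage.
#'
#' @param mesh a [tet_mesh()] from [tetrahedralize()].
#' @param disks list of [build_disk()] objects.
#' @return the mesh with `electrode_weights` and `electrode_nodes` set.
#' @export
embed_electrodes <- function(mesh, disks) {
  if (is.null(mesh$grid))
    stop("mesh lacks structured-grid metadata", call. = FALSE)
  xs <- mesh$grid$xs; ys <- mesh$grid$ys; zs <- mesh$grid$zs
  keep <- mesh$grid$keep; full2kept <- mesh$grid$full2kept
  ncubes <- mesh$grid$ncubes
  ncx <- length(xs) - 1L; ncy <- length(ys) - 1L
  n_nodes <- nrow(mesh$nodes)
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  node_sets <- list()
  for (d_i in seq_along(disks)) {
    d <- disks[[d_i]]
    pts <- d$node_points - matrix(d$normal * 0.05, 73, 3, byrow = TRUE)
    wacc <- numeric(0); jacc <- integer(0)
    for (q in seq_len(73)) {
      p <- pts[q, ]
      ii <- min(max(findInterval(p[1], xs), 1L), ncx)
      jj <- min(max(findInterval(p[2], ys), 1L), ncy)
      kk <- min(max(findInterval(p[3], zs), 1L), length(zs) - 1L)
      cube <- ii + ncx * (jj - 1L) + ncx * ncy * (kk - 1L)
      cand_full <- cube + ncubes * (0:5)          # the cube's 6 Kuhn tets
      cand_full <- cand_full[keep[cand_full]]
      found <- FALSE
      for (tf in cand_full) {
        tk <- full2kept[tf]
        vids <- mesh$tets[tk, ]
        l <- tet_barycentric(p, mesh$nodes[vids, , drop = FALSE])
        if (!is.null(l)) {
          jacc <- c(jacc, vids)
          wacc <- c(wacc, l / 73)
          found <- TRUE
          break
        }
      }
      if (!found)
        stop(sprintf(
          "meshing error: disk node of contact %s at (%.1f, %.1f, %.1f) is not inside the mesh",
          d$label, p[1], p[2], p[3]), call. = FALSE)
    }
    agg <- tapply(wacc, jacc, sum)
    jidx <- as.integer(names(agg))
    w <- as.numeric(agg)
    w <- w / sum(w)                               # rows sum to exactly 1
    trip_i[[d_i]] <- rep(d_i, length(jidx))
    trip_j[[d_i]] <- jidx
    trip_x[[d_i]] <- w
    node_sets[[d$label]] <- jidx
  }
  W <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(length(disks), n_nodes),
    dimnames = list(unname(vapply(disks, function(d) d$label, character(1))), NULL)
  )
  mesh$electrode_weights <- W
  mesh$electrode_nodes <- node_sets
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a
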