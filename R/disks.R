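# Electrode disk and insulating-sheet construction. Each contact is a
# 2.3 mm diameter disk of 73 nodes oriented parallel to the nearest surface
# triangle; the silicone carrier is a 0.5 mm thick sheet draping the
# cortical contour with the disks embedded on its underside.

#' 73-node electrode disk
#'
#' Nodes are arranged as the centre plus concentric rings of 12, 24 and 36
#' points at radii r/3, 2r/3 and r (1 + 12 + 24 + 36 = 73, near-uniform
#' areal density).
#'
#' @param center disk centre (mm).
#' @param normal disk normal (need not be unit; must be non-zero).
#' @param diameter_mm disk diameter (default 2.3 mm).
#' @param label contact label.
#' @return an `electrode_disk`: list with `label`, `center`, `normal`
#'   (unit), `node_points` (73 x 3, mm) and `diameter_mm`.
#' @export
build_disk <- function(center, normal, diameter_mm = 2.3, label = "E1") {
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("disk normal must be non-zero", call. = FALSE)
  normal <- normal / nn
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * normal) * normal
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(normal[2] * t1[3] - normal[3] * t1[2],
          normal[3] * t1[1] - normal[1] * t1[3],
          normal[1] * t1[2] - normal[2] * t1[1])
  r <- diameter_mm / 2
  ring <- function(k, radius) {
    th <- 2 * pi * (seq_len(k) - 1) / k
    outer(cos(th), t1 * radius) + outer(sin(th), t2 * radius)
  }
  local_pts <- rbind(matrix(0, 1, 3), ring(12, r / 3), ring(24, 2 * r / 3),
                     ring(36, r))
  structure(
    list(label = label, center = center, normal = normal,
         node_points = sweep(local_pts, 2, center, "+"),
         diameter_mm = diameter_mm),
    class = "electrode_disk"
  )
}

#' Build disks for all projected contacts
#'
#' Each disk is oriented parallel to the nearest triangle of the closed-gray
#' surface at its (possibly CSF-offset) centroid.
#'
#' @param result a [projection_result()].
#' @param surface the closed-gray [tri_surface()].
#' @param diameter_mm contact diameter.
#' @return named list of [build_disk()] objects.
#' @export
build_disks <- function(result, surface, diameter_mm = 2.3) {
  np <- nearest_surface_point(surface, result$projected_centroids)
  nrm <- face_normals(surface)[np$face, , drop = FALSE]
  out <- lapply(seq_along(result$labels), function(i) {
    build_disk(result$projected_centroids[i, ], nrm[i, ], diameter_mm,
               label = result$labels[i])
  })
  names(out) <- result$labels
  out
}

#' Insulating silicone sheet over the electrode patch
#'
#' A closed solid of the given thickness draping the cortical contour over
#' the patch spanned by the electrode disks (plus a margin), extruded
#' outward along the surface normal. On a planar patch the sheet is a thin
#' box; on a spherical phantom a spherical-shell sector. The disk centres
#' lie on the sheet underside.
#'
#' @param disks list of [build_disk()] objects.
#' @param surface the closed-gray [tri_surface()] (with analytic slab or
#'   sphere description).
#' @param thickness_mm sheet thickness (default 0.5 mm).
#' @param margin_mm lateral margin beyond the outermost disk centres.
#' @return a closed [tri_surface()] named `"sheet"`.
#' @export
build_sheet <- function(disks, surface, thickness_mm = 0.5, margin_mm = 5) {
  centers <- do.call(rbind, lapply(disks, function(d) d$center))
  a <- surface$analytic
  np <- nearest_surface_point(surface, centers)
  if (any(np$dist > 2 * thickness_mm + 2 + 1e-9))
    stop(sprintf(
      "disk centres sit %.2f mm from the surface; sheet would not drape it",
      max(np$dist)), call. = FALSE)
  if (!is.null(a) && a$type == "slab") {
    z0 <- mean(centers[, 3])
    if (max(abs(centers[, 3] - z0)) > 1e-6)
      stop("disk centres are not coplanar over the planar patch", call. = FALSE)
    xl <- range(centers[, 1]) + c(-margin_mm, margin_mm)
    yl <- range(centers[, 2]) + c(-margin_mm, margin_mm)
    return(slab_surface(xl, yl, z0, z0 + thickness_mm, nx = 8, ny = 8,
                        name = "sheet"))
  }
  if (!is.null(a) && a$type == "sphere") {
    v <- sweep(centers, 2, a$center)
    rr <- sqrt(rowSums(v^2))
    R <- mean(rr)
    if (max(abs(rr - R)) > thickness_mm)
      stop("disk centres do not lie on a common spherical shell", call. = FALSE)
    axis <- colMeans(normalize_rows(v))
    axis <- axis / sqrt(sum(axis^2))
    cosang <- normalize_rows(v) %*% axis
    half_angle <- acos(min(cosang)) + margin_mm / R
    return(cap_shell_surface(a$center, axis, c(R, R + thickness_mm),
                             half_angle, name = "sheet"))
  }
  stop("build_sheet requires a planar or spherical cortical surface",
       call. = FALSE)
}

#' Clip cortical tissue above a rigid electrode grid
#'
#' For the rigid model the contacts keep their CT positions, which may sit
#' inside the pre-operative cortex. The gray and closed-gray segmentation
#' voxels lying outboard of the grid's best-fit plane (within the grid
#' footprint plus a margin) are removed so the contacts rest on, not
#' inside, tissue.
#'
#' @param geometry a [head_geometry()].
#' @param electrodes an [electrode_set()] with rigid centroids.
#' @param margin_mm lateral margin of the clipped footprint.
#' @return the [head_geometry()] with gray/closed_gray replaced by the
#'   clipped, re-surfaced masks (voxel-grid analytic description attached).
#' @export
clip_gray_for_rigid <- function(geometry, electrodes, margin_mm = 5) {
  e0 <- electrodes$rigid_centroids
  ctr <- colMeans(e0)
  ev <- eigen(stats::cov(e0), symmetric = TRUE)
  normal <- ev$vectors[, 3]
  # orient outward: away from the cortical interior
  cg <- geometry$surfaces$closed_gray
  inref <- colMeans(cg$vertices)
  if (sum((ctr - inref) * normal) < 0) normal <- -normal
  # in-plane footprint of the grid
  t1 <- ev$vectors[, 1]; t2 <- ev$vectors[, 2]
  loc <- sweep(e0, 2, ctr) %*% cbind(t1, t2)
  pitch <- geometry$voxel_pitch
  out <- geometry
  clipped_any <- FALSE
  for (nm in intersect(c("gray", "closed_gray"), names(geometry$surfaces))) {
    s <- geometry$surfaces[[nm]]
    vg <- if (!is.null(s$analytic) && s$analytic$type == "voxelgrid") {
      structure(list(grid = s$analytic$grid, origin = s$analytic$origin,
                     pitch = s$analytic$pitch), class = "voxel_grid")
    } else voxelize_surface(s, pitch)
    d <- dim(vg$grid)
    cx <- vg$origin[1] + (seq_len(d[1]) - 0.5) * vg$pitch
    cy <- vg$origin[2] + (seq_len(d[2]) - 0.5) * vg$pitch
    cz <- vg$origin[3] + (seq_len(d[3]) - 0.5) * vg$pitch
    pts <- as.matrix(expand.grid(cx, cy, cz))
    h <- sweep(pts, 2, ctr) %*% normal            # height above the grid plane
    l1 <- sweep(pts, 2, ctr) %*% t1
    l2 <- sweep(pts, 2, ctr) %*% t2
    infoot <- l1 >= min(loc[, 1]) - margin_mm & l1 <= max(loc[, 1]) + margin_mm &
      l2 >= min(loc[, 2]) - margin_mm & l2 <= max(loc[, 2]) + margin_mm
    kill <- array(h > 0 & infoot, dim = d)
    if (any(kill & vg$grid)) clipped_any <- TRUE
    vg$grid <- vg$grid & !kill
    ns <- voxel_surface(vg, name = nm)
    out$surfaces[[nm]] <- ns
  }
  if (!clipped_any) {
    warning("electrodes lie outside the tissue; geometry unchanged")
    return(geometry)
  }
  out
}
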