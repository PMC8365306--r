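# Electrode localization under brain shift: the rigid (CT) centroid and
# three methods that project it back onto the closed gray matter surface.
#   * principal axis — each contact independently along the dominant axis of
#     its CT artifact cloud;
#   * Hermes — along the normal of the plane fitted to the contact and its
#     lattice neighbours;
#   * Dykstra — constrained energy minimisation trading off displacement
#     against inter-electrode distance deformation.
# A fourth "rigid" mode keeps the CT geometry and defers to tissue clipping.

#' Projection result
#'
#' @param method one of `"principal_axis"`, `"hermes"`, `"dykstra"`, `"rigid"`.
#' @param labels contact labels.
#' @param projected n x 3 projected centroids e_i (mm).
#' @param rigid n x 3 rigid centroids e_i0 (mm).
#' @param converged logical; may be `FALSE` only for the Dykstra method.
#' @param iterations iteration count (Dykstra), otherwise `NA`.
#' @param fallback logical vector: contacts whose projection ray missed the
#'   surface and fell back to the nearest surface point.
#' @param objective_trace Dykstra energy per accepted iterate.
#' @return an object of class `projection_result` with projection vectors
#'   (`e_i - e_i0`) and Euclidean projection distances precomputed.
#' @export
projection_result <- function(method, labels, projected, rigid,
                              converged = TRUE, iterations = NA_integer_,
                              fallback = rep(FALSE, nrow(projected)),
                              objective_trace = NULL) {
  if (!converged && method != "dykstra")
    stop("non-convergence is only a reportable state for the Dykstra method",
         call. = FALSE)
  vectors <- projected - rigid
  structure(
    list(method = method, labels = labels, projected_centroids = projected,
         rigid_centroids = rigid, projection_vectors = vectors,
         projection_distances = sqrt(rowSums(vectors^2)),
         converged = converged, iterations = iterations, fallback = fallback,
         objective_trace = objective_trace),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf(
    "<projection_result '%s': %d contacts, median projection distance %.2f mm%s>\n",
    x$method, length(x$labels), stats::median(x$projection_distances),
    if (!x$converged) " [NOT CONVERGED]" else ""
  ))
  invisible(x)
}

#' Rigid centroid of an electrode artifact
#'
#' Arithmetic mean of the thresholded CT artifact voxels.
#'
#' @param artifact k x 3 voxel coordinate matrix (mm), k >= 10.
#' @return length-3 centroid (mm).
#' @export
rigid_centroid <- function(artifact) {
  artifact <- rbind(artifact)
  if (nrow(artifact) < 10)
    stop("artifact cloud must contain at least 10 voxels", call. = FALSE)
  colMeans(artifact)
}

# Oriented projection: cast rays from `origin` along +axis and -axis; keep
# the nearer hit. A double miss falls back to the nearest surface point.
project_along_axis <- function(surface, origin, axis) {
  h1 <- first_ray_hit(surface, rbind(origin), rbind(axis))
  h2 <- first_ray_hit(surface, rbind(origin), rbind(-axis))
  t1 <- h1$t; t2 <- h2$t
  if (is.na(t1) && is.na(t2)) {
    np <- nearest_surface_point(surface, rbind(origin))
    return(list(point = np$point[1, ], fallback = TRUE))
  }
  if (is.na(t2) || (!is.na(t1) && t1 <= t2)) {
    list(point = h1$point[1, ], fallback = FALSE)
  } else {
    list(point = h2$point[1, ], fallback = FALSE)
  }
}

#' Principal-axis projection of a single contact
#'
#' The dominant eigenvector of the artifact voxel covariance defines the
#' contact's longitudinal axis; the centroid is projected along it (sign
#' chosen toward the surface) to the first surface intersection.
#'
#' @param artifact k x 3 artifact voxel cloud (mm).
#' @param surface the closed-gray [tri_surface()].
#' @param min_eigen_ratio dominance ratio of the first to second eigenvalue
#'   below which the axis is declared degenerate (default 1.2).
#' @param label contact name used in error messages.
#' @return list with `point` (projected centroid), `direction` (unit axis)
#'   and `fallback` (ray missed; nearest point used).
#' @export
principal_axis_project <- function(artifact, surface, min_eigen_ratio = 1.2,
                                   label = "electrode") {
  ctr <- rigid_centroid(artifact)
  ev <- eigen(stats::cov(artifact), symmetric = TRUE)
  if (ev$values[1] < min_eigen_ratio * ev$values[2])
    stop(sprintf(
      "degenerate artifact axis for %s (eigenvalue ratio %.2f < %.2f)",
      label, ev$values[1] / ev$values[2], min_eigen_ratio
    ), call. = FALSE)
  axis <- ev$vectors[, 1]
  pr <- project_along_axis(surface, ctr, axis)
  list(point = pr$point, direction = axis, fallback = pr$fallback)
}

# Hermes stencil: lattice 4-neighbourhood, topped up with diagonal
# neighbours when fewer than 3 lateral neighbours exist (grid corners), so a
# plane fit always has >= 4 points. Strips use their 1-2 lateral neighbours
# plus a diagonal surrogate that does not exist; handled by the caller.
hermes_stencil <- function(grid_shape) {
  r <- grid_shape[1]; c <- grid_shape[2]
  idx <- function(i, j) as.integer((i - 1L) * c + j)
  lapply(seq_len(r * c), function(k) {
    i <- (k - 1L) %/% c + 1L
    j <- (k - 1L) %% c + 1L
    lat <- list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    lat <- Filter(function(p) p[1] >= 1 && p[1] <= r && p[2] >= 1 && p[2] <= c, lat)
    nb <- vapply(lat, function(p) idx(p[1], p[2]), integer(1))
    if (length(nb) < 3) {
      dia <- list(c(i - 1, j - 1), c(i - 1, j + 1), c(i + 1, j - 1), c(i + 1, j + 1))
      dia <- Filter(function(p) p[1] >= 1 && p[1] <= r && p[2] >= 1 && p[2] <= c, dia)
      dd <- vapply(dia, function(p) idx(p[1], p[2]), integer(1))
      nb <- c(nb, dd[seq_len(min(length(dd), 3 - length(nb)))])
    }
    nb
  })
}

#' Hermes projection
#'
#' For each contact, a total-least-squares plane is fitted to the contact
#' and its lattice neighbours; the contact is projected along the plane
#' normal (oriented toward the surface) to the first intersection.
#'
#' @param electrodes an [electrode_set()] with rigid centroids.
#' @param surface the closed-gray [tri_surface()].
#' @return a [projection_result()] with `method = "hermes"`.
#' @export
hermes_project <- function(electrodes, surface) {
  pos <- electrodes$rigid_centroids
  n <- nrow(pos)
  is_strip <- min(electrodes$grid_shape) == 1L
  stencil <- hermes_stencil(electrodes$grid_shape)
  min_nb <- if (is_strip) 1L else 2L
  if (any(vapply(stencil, length, integer(1)) < min_nb))
    stop("topology error: a contact has fewer than the required lattice neighbours",
         call. = FALSE)
  proj <- matrix(NA_real_, n, 3)
  fb <- logical(n)
  for (k in seq_len(n)) {
    pts <- pos[c(k, stencil[[k]]), , drop = FALSE]
    if (is_strip) {
      # strip stencil: 1-2 collinear neighbours cannot define a plane;
      # combine the strip tangent with the local surface normal
      ev <- eigen(stats::cov(pts), symmetric = TRUE)
      tangent <- ev$vectors[, 1]
      np <- nearest_surface_point(surface, pos[k, , drop = FALSE])
      ns <- face_normals(surface)[np$face[1], ]
      normal <- ns - sum(ns * tangent) * tangent
      nn <- sqrt(sum(normal^2))
      if (nn < 1e-9) normal <- ns else normal <- normal / nn
    } else {
      ev <- eigen(stats::cov(pts), symmetric = TRUE)
      normal <- ev$vectors[, 3]   # smallest-variance direction
    }
    pr <- project_along_axis(surface, pos[k, ], normal)
    proj[k, ] <- pr$point
    fb[k] <- pr$fallback
  }
  projection_result("hermes", electrodes$labels, proj, pos, fallback = fb)
}

# Dykstra energy: displacement + adjacency-weighted spacing deformation.
dykstra_energy <- function(e, e0, adj, d0) {
  d <- sqrt(rowSums((e[adj[, 1], , drop = FALSE] - e[adj[, 2], , drop = FALSE])^2))
  sum((e - e0)^2) + sum((d - d0)^2)
}

#' Dykstra constrained energy-minimising projection
#'
#' Minimises `E = sum_i ||e_i - e_i0||^2 + sum_(i<j) a_ij (d_ij - d_ij0)^2`
#' subject to every contact lying on the closed-gray surface, where `e_i0`
#' are the rigid centroids and `d_ij0` their inter-electrode distances.
#' Solved by damped block-coordinate descent with nearest-point
#' reprojection; an iterate is accepted only if the energy does not
#' increase, so the objective trace is non-increasing. Non-convergence
#' within `max_iter` is a reported state, not an error.
#'
#' @param electrodes an [electrode_set()] with rigid centroids.
#' @param surface the closed-gray [tri_surface()].
#' @param max_iter iteration cap (default 1000).
#' @param tol_mm convergence threshold on the max per-contact movement
#'   (default 0.01 mm).
#' @return a [projection_result()] with `method = "dykstra"`, the objective
#'   trace, and `converged` flag.
#' @export
dykstra_project <- function(electrodes, surface, max_iter = 1000, tol_mm = 0.01) {
  e0 <- electrodes$rigid_centroids
  adj <- electrodes$adjacency
  n <- nrow(e0)
  d0 <- sqrt(rowSums((e0[adj[, 1], , drop = FALSE] - e0[adj[, 2], , drop = FALSE])^2))
  # already optimal? (on the surface with undeformed spacing)
  init_d <- nearest_surface_point(surface, e0)
  if (max(init_d$dist) < 1e-6) {
    return(projection_result("dykstra", electrodes$labels, e0, e0,
                             converged = TRUE, iterations = 0L,
                             objective_trace = 0))
  }
  nbrs <- lapply(seq_len(n), function(i) {
    w1 <- adj[, 1] == i; w2 <- adj[, 2] == i
    list(j = c(adj[w2, 1], adj[w1, 2]), d0 = c(d0[w2], d0[w1]))
  })
  e <- init_d$point
  energy <- dykstra_energy(e, e0, adj, d0)
  trace <- energy
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    e_prev <- e
    for (i in seq_len(n)) {
      nb <- nbrs[[i]]
      dif <- sweep(e[nb$j, , drop = FALSE], 2, e[i, ], "-")
      dn <- sqrt(rowSums(dif^2))
      dn[dn < 1e-9] <- 1e-9
      # pull targets: points at the undeformed distance from each neighbour
      targets <- e[nb$j, , drop = FALSE] - dif / dn * nb$d0
      cand <- (e0[i, ] + colSums(targets)) / (1 + length(nb$j))
      cand <- nearest_surface_point(surface, rbind(cand))$point[1, ]
      e_try <- e; e_try[i, ] <- cand
      en_try <- dykstra_energy(e_try, e0, adj, d0)
      if (en_try <= energy + 1e-12) {
        e <- e_try
        energy <- en_try
      }
    }
    trace <- c(trace, energy)
    if (max(sqrt(rowSums((e - e_prev)^2))) < tol_mm) {
      converged <- TRUE
      break
    }
  }
  projection_result("dykstra", electrodes$labels, e, e0,
                    converged = converged, iterations = iter,
                    objective_trace = trace)
}

#' Rigid localization (no projection)
#'
#' Keeps the CT geometry: projected centroids equal the rigid centroids and
#' all projection distances are zero. Downstream meshing must clip the
#' cortical tissue above the grid (see [clip_gray_for_rigid()]).
#'
#' @param electrodes an [electrode_set()] with rigid centroids.
#' @return a [projection_result()] with `method = "rigid"`.
#' @export
rigid_localize <- function(electrodes) {
  projection_result("rigid", electrodes$labels, electrodes$rigid_centroids,
                    electrodes$rigid_centroids)
}

#' Offset projected contacts into the CSF
#'
#' Moves each projected centroid `depth_mm` along the outward normal of its
#' nearest surface triangle, modelling 0, 1 or 2 mm of cerebrospinal fluid
#' between the contact underside and the cortical surface.
#'
#' @param result a [projection_result()] with contacts on the surface.
#' @param surface the closed-gray [tri_surface()].
#' @param depth_mm CSF depth (mm, >= 0); 0 is the identity.
#' @return the [projection_result()] with offset centroids; projection
#'   vectors/distances remain measured from the rigid centroids.
#' @export
offset_csf <- function(result, surface, depth_mm) {
  if (depth_mm < 0) stop("CSF depth must be >= 0", call. = FALSE)
  if (depth_mm == 0) return(result)
  np <- nearest_surface_point(surface, result$projected_centroids)
  nrm <- face_normals(surface)[np$face, , drop = FALSE]
  out <- result
  out$projected_centroids <- result$projected_centroids + depth_mm * nrm
  out$csf_depth_mm <- depth_mm
  out
}

#' Per-contact projection distances
#'
#' The length of the vector from the rigid centroid to the projected
#' centroid — the per-contact brain-shift metric.
#'
#' @param result a [projection_result()].
#' @return named numeric vector (mm); `summary` attribute carries the
#'   median and IQR.
#' @export
projection_distances <- function(result) {
  d <- result$projection_distances
  names(d) <- result$labels
  attr(d, "summary") <- c(median = stats::median(d),
                          q1 = unname(stats::quantile(d, 0.25)),
                          q3 = unname(stats::quantile(d, 0.75)))
  d
}

#' Inter-electrode distances of the projected contacts
#'
#' Euclidean distance for every lattice-neighbour pair.
#'
#' @param result a [projection_result()].
#' @param adjacency two-column index pair matrix (lattice neighbours).
#' @return numeric vector (mm), one entry per adjacent pair, named
#'   "label1-label2".
#' @export
inter_electrode_distances <- function(result, adjacency) {
  p <- result$projected_centroids
  d <- sqrt(rowSums((p[adjacency[, 1], , drop = FALSE] -
                       p[adjacency[, 2], , drop = FALSE])^2))
  names(d) <- paste0(result$labels[adjacency[, 1]], "-",
                     result$labels[adjacency[, 2]])
  d
}

#' Project a full electrode set with the chosen method
#'
#' Dispatcher used by the pipeline: runs one of the three projection methods
#' (or rigid localization) over all contacts.
#'
#' @param electrodes an [electrode_set()]; principal-axis requires artifact
#'   clouds (see [synthesize_artifacts()]).
#' @param surface the closed-gray [tri_surface()].
#' @param method projection method.
#' @param ... passed to the method (e.g. `max_iter`, `tol_mm` for Dykstra).
#' @return a [projection_result()].
#' @export
project_electrodes <- function(electrodes, surface,
                               method = c("hermes", "principal_axis",
                                          "dykstra", "rigid"), ...) {
  method <- match.arg(method)
  switch(method,
    hermes = hermes_project(electrodes, surface),
    dykstra = dykstra_project(electrodes, surface, ...),
    rigid = rigid_localize(electrodes),
    principal_axis = {
      if (is.null(electrodes$artifacts))
        stop("principal-axis projection requires artifact clouds", call. = FALSE)
      n <- length(electrodes$labels)
      proj <- matrix(NA_real_, n, 3)
      fb <- logical(n)
      for (k in seq_len(n)) {
        pr <- principal_axis_project(electrodes$artifacts[[k]], surface,
                                     label = electrodes$labels[k], ...)
        proj[k, ] <- pr$point
        fb[k] <- pr$fallback
      }
      projection_result("principal_axis", electrodes$labels, proj,
                        electrodes$rigid_centroids, fallback = fb)
    }
  )
}
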