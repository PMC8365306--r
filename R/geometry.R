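#' Triangular surface mesh
#'
#' A `tri_surface` is the geometric substrate of the package: a triangulated
#' tissue boundary with vertices in millimetres. Closed surfaces (every edge
#' shared by exactly two faces, positive enclosed volume) bound a tissue
#' compartment and are the projection targets for electrode localization.
#'
#' @param vertices numeric matrix (n x 3), vertex coordinates in mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices per triangle,
#'   consistently oriented (outward normals for closed surfaces).
#' @param name tissue label (e.g. `"gray"`, `"closed_gray"`, `"csf"`).
#' @param analytic optional analytic description of the enclosed volume used
#'   for fast point classification (see [surface_contains()]); generators
#'   attach one where the geometry is known in closed form.
#' @return an object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, name = "surface", analytic = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("geometry error: face indices out of range", call. = FALSE)
  structure(
    list(vertices = vertices, faces = faces, name = name, analytic = analytic),
    class = "tri_surface"
  )
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf(
    "<tri_surface '%s': %d vertices, %d faces, %s>\n",
    x$name, nrow(x$vertices), nrow(x$faces),
    if (is_closed_surface(x)) sprintf("closed, volume %.1f mm^3", surface_volume(x))
    else "open"
  ))
  invisible(x)
}

face_corners <- function(s) {
  list(
    a = s$vertices[s$faces[, 1], , drop = FALSE],
    b = s$vertices[s$faces[, 2], , drop = FALSE],
    c = s$vertices[s$faces[, 3], , drop = FALSE]
  )
}

row_cross <- function(u, v) {
  cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
}

row_dot <- function(u, v) rowSums(u * v)

row_norm <- function(u) sqrt(rowSums(u * u))

normalize_rows <- function(u) {
  n <- row_norm(u)
  n[n == 0] <- 1
  u / n
}

#' Face normals and centroids
#'
#' @param s a [tri_surface()].
#' @return `face_normals()`: unit outward normals (m x 3) for a consistently
#'   oriented surface; `face_centroids()`: triangle centroids (m x 3).
#' @export
face_normals <- function(s) {
  fc <- face_corners(s)
  normalize_rows(row_cross(fc$b - fc$a, fc$c - fc$a))
}

#' @rdname face_normals
#' @export
face_centroids <- function(s) {
  fc <- face_corners(s)
  (fc$a + fc$b + fc$c) / 3
}

#' Enclosed volume of a closed, outward-oriented surface
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra to the
#' origin); positive for outward orientation.
#'
#' @param s a [tri_surface()].
#' @return volume in mm^3.
#' @export
surface_volume <- function(s) {
  fc <- face_corners(s)
  sum(row_dot(fc$a, row_cross(fc$b, fc$c))) / 6
}

#' Test whether a surface is closed (watertight)
#'
#' Every undirected edge must be used by exactly two faces, with opposite
#' directions (consistent orientation).
#'
#' @param s a [tri_surface()].
#' @return logical.
#' @export
is_closed_surface <- function(s) {
  if (nrow(s$faces) == 0) return(FALSE)
  e <- rbind(s$faces[, 1:2], s$faces[, 2:3], s$faces[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (anyDuplicated(key_dir) > 0) return(FALSE)     # non-manifold or flipped face
  all(table(key_und) == 2L)
}

mean_edge_length <- function(s) {
  fc <- face_corners(s)
  mean(c(row_norm(fc$b - fc$a), row_norm(fc$c - fc$b), row_norm(fc$a - fc$c)))
}

#' Ray / triangle-mesh intersections
#'
#' Vectorised Moller-Trumbore over all (ray, face) pairs, chunked to bound
#' memory. Used for point-in-surface parity tests and for projecting
#' electrodes along an oriented axis onto a cortical surface.
#'
#' @param s a [tri_surface()].
#' @param origins k x 3 matrix of ray origins (mm).
#' @param dirs k x 3 matrix (or a single row recycled) of ray directions.
#' @param chunk number of (ray x face) pairs to process per block.
#' @return data.frame with columns `ray`, `face`, `t` (distance along the
#'   direction, unnormalised by `|dir|` only if dirs are unit) for every hit
#'   with `t > 1e-9`.
#' @export
ray_surface_hits <- function(s, origins, dirs, chunk = 4e6) {
  origins <- rbind(origins)
  dirs <- rbind(dirs)
  if (nrow(dirs) == 1 && nrow(origins) > 1)
    dirs <- dirs[rep(1, nrow(origins)), , drop = FALSE]
  nr <- nrow(origins)
  nf <- nrow(s$faces)
  fc <- face_corners(s)
  e1 <- fc$b - fc$a
  e2 <- fc$c - fc$a
  rays_per_block <- max(1L, floor(chunk / max(nf, 1L)))
  out <- vector("list", ceiling(nr / rays_per_block))
  bi <- 0L
  for (start in seq(1L, nr, by = rays_per_block)) {
    idx <- start:min(nr, start + rays_per_block - 1L)
    k <- length(idx)
    ir <- rep(idx, each = nf)
    jf <- rep(seq_len(nf), times = k)
    O <- origins[ir, , drop = FALSE]
    D <- dirs[ir, , drop = FALSE]
    A <- fc$a[jf, , drop = FALSE]
    E1 <- e1[jf, , drop = FALSE]
    E2 <- e2[jf, , drop = FALSE]
    P <- row_cross(D, E2)
    det <- row_dot(E1, P)
    ok <- abs(det) > 1e-12
    inv <- ifelse(ok, 1 / det, 0)
    Tv <- O - A
    u <- row_dot(Tv, P) * inv
    Q <- row_cross(Tv, E1)
    v <- row_dot(D, Q) * inv
    t <- row_dot(E2, Q) * inv
    hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & t > 1e-9
    if (any(hit)) {
      bi <- bi + 1L
      out[[bi]] <- data.frame(ray = ir[hit], face = jf[hit], t = t[hit])
    }
  }
  if (bi == 0L) return(data.frame(ray = integer(), face = integer(), t = numeric()))
  do.call(rbind, out[seq_len(bi)])
}

#' First ray hit per ray
#'
#' @inheritParams ray_surface_hits
#' @return list with `t`, `point`, `face` (NA where the ray misses).
#' @export
first_ray_hit <- function(s, origins, dirs) {
  origins <- rbind(origins)
  dirs <- rbind(dirs)
  if (nrow(dirs) == 1 && nrow(origins) > 1)
    dirs <- dirs[rep(1, nrow(origins)), , drop = FALSE]
  h <- ray_surface_hits(s, origins, dirs)
  n <- nrow(origins)
  tbest <- rep(NA_real_, n)
  fbest <- rep(NA_integer_, n)
  if (nrow(h) > 0) {
    o <- order(h$ray, h$t)
    h <- h[o, ]
    keep <- !duplicated(h$ray)
    tbest[h$ray[keep]] <- h$t[keep]
    fbest[h$ray[keep]] <- h$face[keep]
  }
  pts <- origins + dirs * tbest
  list(t = tbest, point = pts, face = fbest)
}

# Parity-based point-in-mesh test along a fixed, irrational-ish direction to
# dodge edge/vertex grazing on axis-aligned meshes.
points_in_mesh_parity <- function(s, pts) {
  dir <- c(0.5377671, 0.3612894, 0.7617756)
  dir <- dir / sqrt(sum(dir^2))
  h <- ray_surface_hits(s, pts, matrix(dir, 1))
  cnt <- integer(nrow(rbind(pts)))
  if (nrow(h) > 0) {
    tab <- table(h$ray)
    cnt[as.integer(names(tab))] <- as.integer(tab)
  }
  cnt %% 2L == 1L
}

#' Point-in-surface test
#'
#' Dispatches on the surface's analytic volume description when present
#' (sphere, slab, height-field slab, voxel grid, spherical-shell sector);
#' otherwise falls back to ray-parity counting on the triangulation.
#'
#' @param s a closed [tri_surface()].
#' @param pts k x 3 matrix of query points (mm).
#' @param tol points within `tol` outside are still counted as inside
#'   (analytic paths only).
#' @return logical vector of length k.
#' @export
surface_contains <- function(s, pts, tol = 0) {
  pts <- rbind(pts)
  a <- s$analytic
  if (is.null(a)) return(points_in_mesh_parity(s, pts))
  switch(a$type,
    sphere = {
      r <- sqrt(rowSums(sweep(pts, 2, a$center)^2))
      r <= a$radius + tol
    },
    slab = {
      pts[, 1] >= a$xlim[1] - tol & pts[, 1] <= a$xlim[2] + tol &
        pts[, 2] >= a$ylim[1] - tol & pts[, 2] <= a$ylim[2] + tol &
        pts[, 3] >= a$zlim[1] - tol & pts[, 3] <= a$zlim[2] + tol
    },
    heightfield_slab = {
      zt <- a$top(pts[, 1], pts[, 2])
      pts[, 1] >= a$xlim[1] - tol & pts[, 1] <= a$xlim[2] + tol &
        pts[, 2] >= a$ylim[1] - tol & pts[, 2] <= a$ylim[2] + tol &
        pts[, 3] >= a$zbottom - tol & pts[, 3] <= zt + tol
    },
    voxelgrid = {
      ijk <- sweep(pts, 2, a$origin)
      ijk <- floor(sweep(ijk, 2, rep(a$pitch, 3), "/")) + 1
      d <- dim(a$grid)
      inside <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= d[3]
      res <- logical(nrow(pts))
      if (any(inside)) {
        lin <- ijk[inside, 1] + d[1] * (ijk[inside, 2] - 1) +
          d[1] * d[2] * (ijk[inside, 3] - 1)
        res[inside] <- a$grid[lin]
      }
      res
    },
    shell_sector = {
      v <- sweep(pts, 2, a$center)
      r <- sqrt(rowSums(v^2))
      cosang <- (v %*% a$axis) / pmax(r, 1e-12)
      r >= a$rlim[1] - tol & r <= a$rlim[2] + tol & cosang >= cos(a$half_angle)
    },
    stop("unknown analytic volume type: ", a$type)
  )
}

# Closest points on a set of triangles (Ericson's region test), fully
# vectorised over (point, triangle) pairs. p, a, b, c are k x 3.
closest_point_on_tris <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- row_dot(ab, ap); d2 <- row_dot(ac, ap)
  bp <- p - b
  d3 <- row_dot(ab, bp); d4 <- row_dot(ac, bp)
  cp <- p - c
  d5 <- row_dot(ab, cp); d6 <- row_dot(ac, cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  res <- matrix(NA_real_, nrow(p), 3)
  done <- rep(FALSE, nrow(p))
  set_res <- function(mask, val) {
    m <- mask & !done
    if (any(m)) {
      res[m, ] <<- val[m, , drop = FALSE]
      done[m] <<- TRUE
    }
  }
  set_res(d1 <= 0 & d2 <= 0, a)                                  # vertex A
  set_res(d3 >= 0 & d4 <= d3, b)                                 # vertex B
  set_res(d6 >= 0 & d5 <= d6, c)                                 # vertex C
  vab <- ifelse(abs(d1 - d3) > 0, d1 / (d1 - d3), 0)
  set_res(vc <= 0 & d1 >= 0 & d3 <= 0, a + ab * vab)             # edge AB
  wac <- ifelse(abs(d2 - d6) > 0, d2 / (d2 - d6), 0)
  set_res(vb <= 0 & d2 >= 0 & d6 <= 0, a + ac * wac)             # edge AC
  den_bc <- (d4 - d3) + (d5 - d6)
  wbc <- ifelse(abs(den_bc) > 0, (d4 - d3) / den_bc, 0)
  set_res(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, b + (c - b) * wbc)  # edge BC
  denom <- va + vb + vc
  denom[denom == 0] <- 1
  vv <- vb / denom; ww <- vc / denom
  set_res(rep(TRUE, nrow(p)), a + ab * vv + ac * ww)             # interior
  res
}

#' Nearest point on a surface
#'
#' Exact closest-point projection onto the triangulation, with
#' bounding-sphere culling so repeated projections (e.g. inside the Dykstra
#' iteration) stay cheap.
#'
#' @param s a [tri_surface()].
#' @param pts k x 3 query points (mm).
#' @return list with `point` (k x 3 nearest surface points), `dist`
#'   (Euclidean distances, mm) and `face` (supporting triangle index).
#' @export
nearest_surface_point <- function(s, pts) {
  pts <- rbind(pts)
  fc <- face_corners(s)
  cen <- face_centroids(s)
  crad <- pmax(row_norm(fc$a - cen), row_norm(fc$b - cen), row_norm(fc$c - cen))
  n <- nrow(pts)
  out_p <- matrix(NA_real_, n, 3)
  out_d <- rep(NA_real_, n)
  out_f <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    dc <- sqrt(colSums((t(cen) - pts[i, ])^2))
    bound <- min(dc + crad)
    cand <- which(dc - crad <= bound + 1e-9)
    k <- length(cand)
    P <- matrix(pts[i, ], k, 3, byrow = TRUE)
    cpt <- closest_point_on_tris(
      P, fc$a[cand, , drop = FALSE], fc$b[cand, , drop = FALSE],
      fc$c[cand, , drop = FALSE]
    )
    dd <- sqrt(rowSums((cpt - P)^2))
    j <- which.min(dd)
    out_p[i, ] <- cpt[j, ]
    out_d[i] <- dd[j]
    out_f[i] <- cand[j]
  }
  list(point = out_p, dist = out_d, face = out_f)
}

# Restore the RNG state on exit so seeded generators do not perturb the
# caller's random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
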