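# Parametric surface generators: subdivided icospheres and (height-field)
# slabs. These are the analytic substrates the head phantoms are built from.

#' Subdivided icosphere
#'
#' @param radius sphere radius (mm).
#' @param center sphere centre (length-3, mm).
#' @param mesh_edge_mm target triangle edge length; the subdivision level is
#'   chosen so the realised edge length does not exceed it.
#' @param name tissue label.
#' @return a closed [tri_surface()] with an analytic sphere description.
#' @export
icosphere <- function(radius, center = c(0, 0, 0), mesh_edge_mm = 3,
                      name = "sphere") {
  if (radius <= 0 || mesh_edge_mm <= 0)
    stop("geometry error: radius and mesh_edge_mm must be positive", call. = FALSE)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  # icosahedron edge on the unit sphere is ~1.0515; each subdivision halves it
  edge0 <- 1.05146 * radius
  nsub <- max(0, ceiling(log2(edge0 / mesh_edge_mm)))
  for (i in seq_len(nsub)) {
    edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    ukey <- unique(key)
    eidx <- match(key, ukey)
    ue <- edges[!duplicated(key), , drop = FALSE]
    mid <- normalize_rows((v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2)
    midid <- nrow(v) + seq_len(nrow(mid))
    v <- rbind(v, mid)
    nf <- nrow(f)
    m12 <- midid[eidx[seq_len(nf)]]
    m23 <- midid[eidx[nf + seq_len(nf)]]
    m31 <- midid[eidx[2 * nf + seq_len(nf)]]
    f <- rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31)
    )
  }
  verts <- sweep(v * radius, 2, center, "+")
  tri_surface(verts, f, name = name,
              analytic = list(type = "sphere", center = center, radius = radius))
}

# Triangulate an (nx+1) x (ny+1) grid of vertex indices laid out column-major
# (x fastest). Diagonals split consistently (lower-left to upper-right).
grid_faces <- function(nx, ny, up = TRUE) {
  ix <- rep(seq_len(nx), ny)
  iy <- rep(seq_len(ny), each = nx)
  v00 <- (iy - 1) * (nx + 1) + ix
  v10 <- v00 + 1
  v01 <- v00 + (nx + 1)
  v11 <- v01 + 1
  f <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  if (!up) f <- f[, c(1, 3, 2)]
  f
}

#' Closed slab surface with an optional height-field top
#'
#' Builds a watertight box whose top face follows `top(x, y)`; used for the
#' planar and gyral phantoms. Bottom and sides are flat.
#'
#' @param xlim,ylim lateral extents (mm).
#' @param zbottom bottom plane (mm).
#' @param top either a single number (flat top) or a function `f(x, y)`
#'   returning the top height (mm), which must stay above `zbottom`.
#' @param nx,ny grid resolution of the top/bottom faces.
#' @param name tissue label.
#' @return a closed [tri_surface()] with an analytic slab description.
#' @export
slab_surface <- function(xlim, ylim, zbottom, top, nx = 40, ny = 40,
                         name = "slab") {
  xs <- seq(xlim[1], xlim[2], length.out = nx + 1)
  ys <- seq(ylim[1], ylim[2], length.out = ny + 1)
  gx <- rep(xs, times = ny + 1)
  gy <- rep(ys, each = nx + 1)
  flat <- !is.function(top)
  topf <- if (flat) {
    ztop <- top
    function(x, y) rep(ztop, length(x))
  } else top
  zt <- topf(gx, gy)
  if (any(zt <= zbottom))
    stop("geometry error: top surface dips to or below the slab bottom", call. = FALSE)
  nvg <- (nx + 1) * (ny + 1)
  vt <- cbind(gx, gy, zt)
  vb <- cbind(gx, gy, zbottom)
  v <- rbind(vt, vb)
  f_top <- grid_faces(nx, ny, up = TRUE)
  f_bot <- grid_faces(nx, ny, up = FALSE) + nvg
  # side walls: boundary vertices of the top grid connect to matching bottom
  ring <- c(
    seq_len(nx + 1),                                   # y = ymin, x increasing
    seq(2 * (nx + 1), (ny + 1) * (nx + 1), by = nx + 1),   # x = xmax, y increasing
    seq((ny + 1) * (nx + 1) - 1, ny * (nx + 1) + 1, by = -1),  # y = ymax, x decreasing
    seq((ny - 1) * (nx + 1) + 1, nx + 2, by = -(nx + 1))       # x = xmin, y decreasing
  )
  nb <- length(ring)
  nxt <- c(ring[-1], ring[1])
  f_side <- rbind(
    cbind(ring, nxt + nvg, nxt),
    cbind(ring, ring + nvg, nxt + nvg)
  )
  f <- rbind(f_top, f_bot, f_side)
  analytic <- if (flat) {
    list(type = "slab", xlim = xlim, ylim = ylim, zlim = c(zbottom, ztop))
  } else {
    list(type = "heightfield_slab", xlim = xlim, ylim = ylim,
         zbottom = zbottom, top = topf)
  }
  s <- tri_surface(v, f, name = name, analytic = analytic)
  if (surface_volume(s) < 0) s$faces <- s$faces[, c(1, 3, 2)]
  s
}

#' Closed spherical shell sector ("cap shell")
#'
#' The solid bounded by two concentric spherical caps (radii `rlim`) and the
#' cone of half-angle `half_angle` about `axis`; models the insulating sheet
#' draped over a spherical cortical phantom.
#'
#' @param center sphere centre (mm).
#' @param axis unit vector through the cap centre.
#' @param rlim inner/outer radii (mm).
#' @param half_angle angular footprint (radians).
#' @param n_ring,n_rad angular resolution.
#' @param name label.
#' @return a closed [tri_surface()].
#' @export
cap_shell_surface <- function(center, axis, rlim, half_angle,
                              n_ring = 48, n_rad = 16, name = "sheet") {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    axis[2] * e1[3] - axis[3] * e1[2],
    axis[3] * e1[1] - axis[1] * e1[3],
    axis[1] * e1[2] - axis[2] * e1[1]
  )
  cap_points <- function(r) {
    # polar grid: apex + rings
    th <- seq(0, half_angle, length.out = n_rad + 1)[-1]
    ph <- seq(0, 2 * pi, length.out = n_ring + 1)[-1]
    ring_pts <- do.call(rbind, lapply(th, function(t1) {
      d <- outer(cos(ph), e1) * sin(t1) + outer(sin(ph), e2) * sin(t1) +
        matrix(axis * cos(t1), n_ring, 3, byrow = TRUE)
      d * r
    }))
    sweep(rbind(axis * r, ring_pts), 2, center, "+")
  }
  cap_faces <- function(offset, up = TRUE) {
    f <- list()
    apex <- 1
    first_ring <- 1 + seq_len(n_ring)
    nxt <- c(first_ring[-1], first_ring[1])
    f[[1]] <- cbind(apex, first_ring, nxt)
    for (i in seq_len(n_rad - 1)) {
      r0 <- 1 + (i - 1) * n_ring + seq_len(n_ring)
      r1 <- r0 + n_ring
      n0 <- c(r0[-1], r0[1]); n1 <- c(r1[-1], r1[1])
      f[[i + 1]] <- rbind(cbind(r0, r1, n1), cbind(r0, n1, n0))
    }
    f <- do.call(rbind, f)
    if (!up) f <- f[, c(1, 3, 2)]
    f + offset
  }
  npc <- 1 + n_rad * n_ring
  v <- rbind(cap_points(rlim[2]), cap_points(rlim[1]))
  f_out <- cap_faces(0, up = TRUE)
  f_in <- cap_faces(npc, up = FALSE)
  rim_out <- 1 + (n_rad - 1) * n_ring + seq_len(n_ring)
  rim_in <- rim_out + npc
  nxo <- c(rim_out[-1], rim_out[1]); nxi <- c(rim_in[-1], rim_in[1])
  f_rim <- rbind(cbind(nxo, rim_out, rim_in), cbind(nxo, rim_in, nxi))
  s <- tri_surface(v, rbind(f_out, f_in, f_rim), name = name,
                   analytic = list(type = "shell_sector", center = center,
                                   axis = axis, rlim = rlim,
                                   half_angle = half_angle))
  if (surface_volume(s) < 0) s$faces <- s$faces[, c(1, 3, 2)]
  s
}
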