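# Rasterization and 3-D binary morphology. The closing filter that produces
# the "closed gray matter" surface operates on a voxelized segmentation
# (dilation then erosion with a ball structuring element), mirroring how the
# clinical pipeline closes sulci on the volumetric gray-matter mask. The
# dilation/erosion are computed by FFT convolution with the ball kernel;
# the closed mask is re-surfaced by boundary-face (cuberille) extraction.

#' Rasterize a closed surface onto a regular voxel grid
#'
#' @param s a closed [tri_surface()].
#' @param pitch voxel edge length (mm).
#' @param pad number of empty voxels of padding around the bounding box.
#' @return a `voxel_grid`: list with logical 3-D `grid`, `origin` (corner of
#'   voxel \[1,1,1\], mm) and `pitch`. Voxel centres are classified.
#' @export
voxelize_surface <- function(s, pitch, pad = 2L) {
  stopifnot(pitch > 0)
  lo <- apply(s$vertices, 2, min) - pad * pitch
  hi <- apply(s$vertices, 2, max) + pad * pitch
  nx <- ceiling((hi - lo) / pitch)
  ctr <- lapply(1:3, function(k) lo[k] + (seq_len(nx[k]) - 0.5) * pitch)
  pts <- as.matrix(expand.grid(ctr[[1]], ctr[[2]], ctr[[3]]))
  inside <- surface_contains(s, pts)
  grid <- array(inside, dim = nx)
  structure(list(grid = grid, origin = lo, pitch = pitch), class = "voxel_grid")
}

ball_kernel_fft <- function(dims, r_vox) {
  # ball of radius r_vox in voxel units, wrapped so its centre sits at [1,1,1]
  offs <- lapply(dims, function(n) {
    ix <- seq_len(n) - 1
    pmin(ix, n - ix)      # circular distance to index 0
  })
  d2 <- outer(outer(offs[[1]]^2, offs[[2]]^2, "+"), offs[[3]]^2, "+")
  k <- array(as.numeric(d2 <= r_vox^2 + 1e-9), dim = dims)
  fft(k)
}

conv_count <- function(a_num, kf) {
  # circular convolution counts via FFT (inputs padded by caller)
  re <- Re(fft(fft(a_num) * kf, inverse = TRUE)) / length(a_num)
  re
}

pad_grid <- function(g, pad, fill = FALSE) {
  d <- dim(g)
  out <- array(fill, dim = d + 2 * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- g
  out
}

unpad_grid <- function(g, pad, d) {
  g[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])]
}

#' Binary dilation / erosion / closing with a ball structuring element
#'
#' @param vg a `voxel_grid` (see [voxelize_surface()]).
#' @param radius_mm structuring-element radius (mm).
#' @return a `voxel_grid` of identical shape. Dilation marks every voxel
#'   whose centre lies within `radius_mm` of an occupied voxel centre;
#'   erosion is its morphological dual; closing is dilation then erosion.
#' @export
voxel_dilate <- function(vg, radius_mm) {
  r <- radius_mm / vg$pitch
  if (r <= 0) return(vg)
  pad <- ceiling(r) + 1L
  d <- dim(vg$grid)
  a <- pad_grid(vg$grid, pad, FALSE)
  kf <- ball_kernel_fft(dim(a), r)
  cnt <- conv_count(array(as.numeric(a), dim = dim(a)), kf)
  vg$grid <- unpad_grid(cnt > 0.5, pad, d)
  vg
}

#' @rdname voxel_dilate
#' @export
voxel_erode <- function(vg, radius_mm) {
  r <- radius_mm / vg$pitch
  if (r <= 0) return(vg)
  pad <- ceiling(r) + 1L
  d <- dim(vg$grid)
  a <- pad_grid(!vg$grid, pad, TRUE)     # complement, padded as empty tissue
  kf <- ball_kernel_fft(dim(a), r)
  cnt <- conv_count(array(as.numeric(a), dim = dim(a)), kf)
  vg$grid <- unpad_grid(!(cnt > 0.5), pad, d)
  vg
}

#' @rdname voxel_dilate
#' @export
voxel_close <- function(vg, radius_mm) {
  voxel_erode(voxel_dilate(vg, radius_mm), radius_mm)
}

#' Extract the boundary surface of a voxel grid (cuberille)
#'
#' Emits two triangles for every voxel face between an occupied and an empty
#' voxel. The result is closed, outward-oriented, and its enclosed volume is
#' exactly `sum(grid) * pitch^3`. The voxel grid itself is attached as the
#' surface's analytic volume description, so point classification against
#' the re-surfaced mask is a constant-time lookup.
#'
#' @param vg a `voxel_grid`.
#' @param name tissue label for the resulting surface.
#' @return a closed [tri_surface()].
#' @export
voxel_surface <- function(vg, name = "voxel_surface") {
  g <- vg$grid
  d <- dim(g)
  gp <- pad_grid(g, 1L, FALSE)
  occ <- which(gp)
  dp <- dim(gp)
  idx <- arrayInd(occ, dp)
  stride <- c(1L, dp[1], dp[1] * dp[2])
  quads <- list()
  qi <- 0L
  # corner offsets of the unit cube, in grid units relative to voxel corner
  corner <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1)
  )
  # for each face direction: neighbour offset and the 4 cube corners (CCW
  # viewed from outside)
  face_def <- list(
    list(off = c(-1, 0, 0), corners = c(1, 5, 7, 3)),
    list(off = c(+1, 0, 0), corners = c(2, 4, 8, 6)),
    list(off = c(0, -1, 0), corners = c(1, 2, 6, 5)),
    list(off = c(0, +1, 0), corners = c(3, 7, 8, 4)),
    list(off = c(0, 0, -1), corners = c(1, 3, 4, 2)),
    list(off = c(0, 0, +1), corners = c(5, 6, 8, 7))
  )
  for (fd in face_def) {
    nb <- occ + sum(fd$off * stride)
    expose <- !gp[nb]
    if (!any(expose)) next
    base <- idx[expose, , drop = FALSE] - 1L   # voxel corner in padded units
    cs <- lapply(fd$corners, function(ci) {
      sweep(base, 2, corner[ci, ], "+")
    })
    qi <- qi + 1L
    quads[[qi]] <- cs
  }
  if (qi == 0L) stop("geometry error: empty voxel grid", call. = FALSE)
  # collect vertices (grid corner coordinates in padded units)
  allc <- do.call(rbind, lapply(quads, function(cs) do.call(rbind, cs)))
  keys <- allc[, 1] + (dp[1] + 1) * (allc[, 2] + (dp[2] + 1) * allc[, 3])
  ukeys <- unique(keys)
  vid <- match(keys, ukeys)
  uverts <- allc[!duplicated(keys), , drop = FALSE]
  # padded-unit corner -> mm: corner (1,1,1) of padded grid sits at origin - pitch
  verts <- sweep((uverts - 1) * vg$pitch, 2, vg$origin, "+")
  # rebuild per-quad corner ids
  nq_per <- vapply(quads, function(cs) nrow(cs[[1]]), integer(1))
  faces <- vector("list", qi)
  pos <- 0L
  for (i in seq_len(qi)) {
    n <- nq_per[i]
    c1 <- vid[pos + seq_len(n)]
    c2 <- vid[pos + n + seq_len(n)]
    c3 <- vid[pos + 2 * n + seq_len(n)]
    c4 <- vid[pos + 3 * n + seq_len(n)]
    faces[[i]] <- rbind(cbind(c1, c2, c3), cbind(c1, c3, c4))
    pos <- pos + 4L * n
  }
  analytic <- list(type = "voxelgrid", grid = vg$grid, origin = vg$origin,
                   pitch = vg$pitch)
  tri_surface(verts, do.call(rbind, faces), name = name, analytic = analytic)
}

#' Voxel-grid volume
#' @param vg a `voxel_grid`.
#' @return occupied volume in mm^3.
#' @export
voxel_volume <- function(vg) sum(vg$grid) * vg$pitch^3
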