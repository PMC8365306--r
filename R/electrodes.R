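#' Labelled ECoG electrode set
#'
#' Holds the grid/strip contacts with their ground-truth ("true") centroids
#' on the cortical surface, the rigid (CT-derived, brain-shifted) centroids,
#' lattice adjacency, and optional per-contact artifact voxel clouds.
#' Labels follow the clinical convention: rows A, B, C, ... and columns
#' 1, 2, ... ("A1".."H8" for an 8 x 8 grid).
#'
#' @param labels character vector of contact labels.
#' @param grid_shape `c(rows, cols)`; a strip is `c(1, n)`.
#' @param true_centroids n x 3 matrix of on-surface contact centres (mm), or
#'   `NULL` when only CT-derived positions exist.
#' @param rigid_centroids n x 3 matrix of rigid centroids (mm).
#' @param normals n x 3 outward surface normals at the true centroids.
#' @param adjacency two-column integer matrix of lattice-neighbour index
#'   pairs (i < j).
#' @param contact_diameter_mm exposed contact diameter (default 2.3 mm).
#' @param pitch_mm centre-to-centre spacing (default 10 mm).
#' @param artifacts optional named list of per-contact voxel clouds (k x 3).
#' @param center optional centre of curvature (sphere phantoms), used by the
#'   radial brain-shift mode.
#' @return an object of class `electrode_set`.
#' @export
electrode_set <- function(labels, grid_shape, true_centroids, rigid_centroids,
                          normals, adjacency, contact_diameter_mm = 2.3,
                          pitch_mm = 10, artifacts = NULL, center = NULL) {
  n <- length(labels)
  stopifnot(contact_diameter_mm > 0, pitch_mm > 0)
  if (!is.null(true_centroids)) stopifnot(nrow(true_centroids) == n)
  stopifnot(nrow(rigid_centroids) == n, nrow(normals) == n)
  if (nrow(adjacency) > 0) {
    stopifnot(ncol(adjacency) == 2, all(adjacency >= 1), all(adjacency <= n),
              all(adjacency[, 1] != adjacency[, 2]))
  }
  structure(
    list(labels = labels, grid_shape = grid_shape,
         true_centroids = true_centroids, rigid_centroids = rigid_centroids,
         normals = normals, adjacency = adjacency,
         contact_diameter_mm = contact_diameter_mm, pitch_mm = pitch_mm,
         artifacts = artifacts, center = center),
    class = "electrode_set"
  )
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf(
    "<electrode_set: %d contacts (%s), pitch %g mm, diameter %g mm%s>\n",
    length(x$labels), paste(x$grid_shape, collapse = "x"), x$pitch_mm,
    x$contact_diameter_mm,
    if (!is.null(x$artifacts)) ", with artifacts" else ""
  ))
  invisible(x)
}

#' Grid labels and lattice adjacency
#'
#' Adjacency is the symmetric, irreflexive 4-neighbour lattice relation:
#' contacts adjacent along rows or columns only (the `a_ij` weights of the
#' energy-minimising projection). An `r x c` grid has `r(c-1) + c(r-1)`
#' neighbour pairs.
#'
#' @param grid_shape `c(rows, cols)`.
#' @return `grid_labels()`: character labels row-major ("A1", "A2", ...);
#'   `grid_adjacency()`: two-column matrix of index pairs with i < j.
#' @export
grid_labels <- function(grid_shape) {
  r <- grid_shape[1]; c <- grid_shape[2]
  stopifnot(r >= 1, c >= 1, r <= 26)
  as.vector(t(outer(LETTERS[seq_len(r)], seq_len(c), paste0)))
}

#' @rdname grid_labels
#' @export
grid_adjacency <- function(grid_shape) {
  r <- grid_shape[1]; c <- grid_shape[2]
  idx <- function(i, j) (i - 1L) * c + j    # row-major, matching grid_labels
  pairs <- list()
  k <- 0L
  if (c > 1) {
    i <- rep(seq_len(r), each = c - 1L)
    j <- rep(seq_len(c - 1L), times = r)
    k <- k + 1L
    pairs[[k]] <- cbind(idx(i, j), idx(i, j + 1L))
  }
  if (r > 1) {
    i <- rep(seq_len(r - 1L), each = c)
    j <- rep(seq_len(c), times = r - 1L)
    k <- k + 1L
    pairs[[k]] <- cbind(idx(i, j), idx(i + 1L, j))
  }
  out <- do.call(rbind, pairs)
  out[out[, 1] > out[, 2], ] <- out[out[, 1] > out[, 2], c(2, 1)]
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Third point on the sphere |p|=R at chord c from both a and b (Chebyshev-net
# step). `prev` disambiguates the two solutions: the new point continues away
# from it.
chebyshev_step <- function(a, b, R, c, center, prev) {
  a0 <- a - center; b0 <- b - center; p0 <- prev - center
  lam <- (2 * R^2 - c^2) / (2 * (R^2 + sum(a0 * b0)))
  nvec <- c(
    a0[2] * b0[3] - a0[3] * b0[2],
    a0[3] * b0[1] - a0[1] * b0[3],
    a0[1] * b0[2] - a0[2] * b0[1]
  )
  s <- lam * (a0 + b0)
  g2 <- (R^2 - sum(s * s)) / sum(nvec * nvec)
  if (g2 < 0) stop("geometry error: grid footprint does not fit on the sphere",
                   call. = FALSE)
  g <- sqrt(g2)
  cand1 <- s + g * nvec
  cand2 <- s - g * nvec
  p <- if (sum((cand1 - p0)^2) >= sum((cand2 - p0)^2)) cand1 else cand2
  p + center
}

#' Place an ECoG grid on the closed-gray surface
#'
#' Contacts are laid out with exact centre-to-centre pitch. On a planar
#' patch the lattice is Euclidean; on a spherical phantom a Chebyshev-net
#' construction marches the first row and column along great circles and
#' intersects chord-circles for interior contacts, so every lattice edge
#' keeps the exact 10 mm geodesic spacing (the physical grid is inextensible
#' but can shear).
#'
#' @param geometry a [head_geometry()] whose `closed_gray` surface carries an
#'   analytic slab or sphere description.
#' @param grid_shape `c(rows, cols)`.
#' @param pitch_mm centre-to-centre spacing (mm).
#' @param anchor optional list with `point` (grid centre for planar; apex
#'   direction for spherical) and `u`, `v` tangent directions.
#' @param contact_diameter_mm contact diameter (mm).
#' @return an [electrode_set()] with true centroids on the surface and rigid
#'   centroids initialised to the true positions (no brain shift yet).
#' @export
place_grid <- function(geometry, grid_shape = c(8, 8), pitch_mm = 10,
                       anchor = NULL, contact_diameter_mm = 2.3) {
  surf <- geometry$surfaces$closed_gray
  if (is.null(surf)) stop("geometry error: no closed_gray surface", call. = FALSE)
  a <- surf$analytic
  r <- grid_shape[1]; c <- grid_shape[2]
  labels <- grid_labels(grid_shape)
  adj <- grid_adjacency(grid_shape)
  off_r <- (seq_len(r) - (r + 1) / 2) * pitch_mm
  off_c <- (seq_len(c) - (c + 1) / 2) * pitch_mm
  if (!is.null(a) && a$type %in% c("slab", "heightfield_slab")) {
    ztop <- if (a$type == "slab") a$zlim[2] else NA
    if (is.na(ztop)) stop("geometry error: grid placement needs a flat top",
                          call. = FALSE)
    ctr <- if (is.null(anchor)) c(mean(a$xlim), mean(a$ylim), ztop) else anchor$point
    u <- if (is.null(anchor)) c(1, 0, 0) else anchor$u
    v <- if (is.null(anchor)) c(0, 1, 0) else anchor$v
    pos <- matrix(NA_real_, r * c, 3)
    for (i in seq_len(r)) for (j in seq_len(c)) {
      pos[(i - 1) * c + j, ] <- ctr + off_r[i] * u + off_c[j] * v
    }
    margin <- contact_diameter_mm / 2
    if (any(pos[, 1] < a$xlim[1] + margin | pos[, 1] > a$xlim[2] - margin |
              pos[, 2] < a$ylim[1] + margin | pos[, 2] > a$ylim[2] - margin))
      stop("geometry error: grid footprint exceeds the surface patch",
           call. = FALSE)
    normals <- matrix(c(0, 0, 1), r * c, 3, byrow = TRUE)
    return(electrode_set(labels, grid_shape, pos, pos, normals, adj,
                         contact_diameter_mm, pitch_mm))
  }
  if (!is.null(a) && a$type == "sphere") {
    R <- a$radius
    axis <- if (is.null(anchor)) c(0, 0, 1) else anchor$point / sqrt(sum(anchor$point^2))
    ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    if ((max(abs(off_r)) + max(abs(off_c))) * 1.05 >= pi * R / 2)
      stop("geometry error: grid footprint exceeds the surface patch",
           call. = FALSE)
    chord <- 2 * R * sin(pitch_mm / (2 * R))
    pos <- matrix(NA_real_, r * c, 3)
    id <- function(i, j) (i - 1L) * c + j
    step_geo <- function(p0, t0, s) {
      # great-circle march on the unit sphere with parallel-transported tangent
      list(p = cos(s / R) * p0 + sin(s / R) * t0,
           t = -sin(s / R) * p0 + cos(s / R) * t0)
    }
    # net corner: back off from the apex along e1, then along e2. e2 is the
    # plane normal of the first march, and the transported e1 the plane
    # normal of the second, so both stay parallel-transported exactly.
    m1 <- step_geo(axis, e1, off_r[1])
    m2 <- step_geo(m1$p, e2, off_c[1])
    p <- m2$p; t <- m1$t        # first column: march along the e1 direction
    for (i in seq_len(r)) {
      pos[id(i, 1), ] <- a$center + R * p
      st <- step_geo(p, t, pitch_mm); p <- st$p; t <- st$t
    }
    p <- m2$p; t <- m2$t        # first row: march along the e2 direction
    for (j in seq_len(c)) {
      pos[id(1, j), ] <- a$center + R * p
      st <- step_geo(p, t, pitch_mm); p <- st$p; t <- st$t
    }
    for (i in 2:r) for (j in 2:c) {
      pos[id(i, j), ] <- chebyshev_step(
        pos[id(i - 1, j), ], pos[id(i, j - 1), ], R, chord, a$center,
        prev = pos[id(i - 1, j - 1), ]
      )
    }
    normals <- normalize_rows(sweep(pos, 2, a$center))
    return(electrode_set(labels, grid_shape, pos, pos, normals, adj,
                         contact_diameter_mm, pitch_mm, center = a$center))
  }
  stop("geometry error: place_grid requires a planar or spherical closed_gray",
       call. = FALSE)
}

#' Brain-shift model
#'
#' Synthetic surrogate for post-implantation brain shift: contacts observed
#' in CT appear displaced inward relative to the pre-operative cortical
#' surface by a uniform magnitude, with independent isotropic per-contact
#' jitter.
#'
#' @param magnitude_mm uniform inward displacement (mm, >= 0).
#' @param jitter_sd_mm per-contact isotropic Gaussian jitter SD (mm, >= 0).
#' @param direction_mode `"surface-normal"` (inward along the local surface
#'   normal) or `"radial"` (toward the centre of curvature).
#' @param seed integer RNG seed; identical seeds reproduce identical shifts.
#' @return an object of class `shift_model`.
#' @export
shift_model <- function(magnitude_mm, jitter_sd_mm = 0,
                        direction_mode = c("surface-normal", "radial"),
                        seed = 1L) {
  direction_mode <- match.arg(direction_mode)
  if (magnitude_mm < 0) stop("shift magnitude must be >= 0", call. = FALSE)
  if (jitter_sd_mm < 0) stop("jitter SD must be >= 0", call. = FALSE)
  structure(list(magnitude_mm = magnitude_mm, jitter_sd_mm = jitter_sd_mm,
                 direction_mode = direction_mode, seed = as.integer(seed)),
            class = "shift_model")
}

#' Apply simulated brain shift to an electrode set
#'
#' Displaces the rigid centroids inward from the true on-surface positions;
#' the true centroids are retained as ground truth for recovery tests.
#'
#' @param electrodes an [electrode_set()] with true centroids.
#' @param shift a [shift_model()].
#' @return the electrode set with updated `rigid_centroids`.
#' @export
apply_brain_shift <- function(electrodes, shift) {
  stopifnot(inherits(shift, "shift_model"))
  if (is.null(electrodes$true_centroids))
    stop("true centroids required to apply brain shift", call. = FALSE)
  n <- nrow(electrodes$true_centroids)
  dirs <- switch(shift$direction_mode,
    "surface-normal" = -electrodes$normals,
    "radial" = {
      ctr <- if (is.null(electrodes$center)) c(0, 0, 0) else electrodes$center
      normalize_rows(sweep(electrodes$true_centroids, 2, ctr) * -1)
    }
  )
  jitter <- with_seed(shift$seed, {
    matrix(stats::rnorm(3 * n, sd = shift$jitter_sd_mm), n, 3)
  })
  electrodes$rigid_centroids <- electrodes$true_centroids +
    shift$magnitude_mm * dirs + jitter
  electrodes
}

#' Synthesize CT-like electrode artifacts
#'
#' Each contact gains an elongated Gaussian voxel cloud centred exactly on
#' its rigid centroid, whose covariance is dominated by the supplied axis
#' (metal-artifact streak direction in the CT). The cloud feeds the rigid
#' centroid computation and the principal-axis projection.
#'
#' @param electrodes an [electrode_set()].
#' @param axis_hint per-contact direction matrix (n x 3) or a single row.
#' @param elongation ratio of axial to transverse SD; must exceed 1.
#' @param n_voxels voxels per cloud (>= 10).
#' @param seed RNG seed.
#' @param transverse_sd_mm transverse cloud SD (mm); default 0.6, on the
#'   order of the contact radius.
#' @return the electrode set with `artifacts` populated.
#' @export
synthesize_artifacts <- function(electrodes, axis_hint, elongation = 4,
                                 n_voxels = 60, seed = 1L,
                                 transverse_sd_mm = 0.6) {
  if (elongation <= 1)
    stop("elongation must exceed 1 (near-isotropic clouds have no axis)",
         call. = FALSE)
  if (n_voxels < 10)
    stop("n_voxels must be >= 10 (degenerate covariance)", call. = FALSE)
  n <- length(electrodes$labels)
  axis_hint <- rbind(axis_hint)
  if (nrow(axis_hint) == 1) axis_hint <- axis_hint[rep(1, n), , drop = FALSE]
  axis_hint <- normalize_rows(axis_hint)
  arts <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ax <- axis_hint[i, ]
      ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      t1 <- ref - sum(ref * ax) * ax; t1 <- t1 / sqrt(sum(t1^2))
      t2 <- c(ax[2] * t1[3] - ax[3] * t1[2],
              ax[3] * t1[1] - ax[1] * t1[3],
              ax[1] * t1[2] - ax[2] * t1[1])
      loc <- cbind(stats::rnorm(n_voxels, sd = transverse_sd_mm * elongation),
                   stats::rnorm(n_voxels, sd = transverse_sd_mm),
                   stats::rnorm(n_voxels, sd = transverse_sd_mm))
      cloud <- loc[, 1] %o% ax + loc[, 2] %o% t1 + loc[, 3] %o% t2
      # recentre exactly: the cloud centroid IS the rigid centroid
      cloud <- sweep(cloud, 2, colMeans(cloud))
      sweep(cloud, 2, electrodes$rigid_centroids[i, ], "+")
    })
  })
  names(arts) <- electrodes$labels
  electrodes$artifacts <- arts
  electrodes
}
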