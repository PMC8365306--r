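#' Head phantom geometry
#'
#' A `head_geometry` bundles the nested tissue surfaces the volume-conduction
#' model is built from, ordered inside-out (e.g. white, gray, closed_gray,
#' csf). The closed-gray surface (sulci filled by morphological closing) is
#' the projection target for electrode localization; the CSF surface bounds
#' the outermost conductive compartment.
#'
#' @param surfaces named list of [tri_surface()], ordered inner to outer.
#' @param voxel_pitch voxel size (mm) used by morphological operations.
#' @return an object of class `head_geometry`.
#' @export
head_geometry <- function(surfaces, voxel_pitch = 1) {
  stopifnot(is.list(surfaces), length(surfaces) >= 1, voxel_pitch > 0)
  if (is.null(names(surfaces)) || any(!nzchar(names(surfaces))))
    stop("geometry error: surfaces must be named", call. = FALSE)
  structure(list(surfaces = surfaces, voxel_pitch = voxel_pitch),
            class = "head_geometry")
}

#' @export
print.head_geometry <- function(x, ...) {
  cat(sprintf("<head_geometry: %s; voxel pitch %g mm>\n",
              paste(names(x$surfaces), collapse = " < "), x$voxel_pitch))
  invisible(x)
}

#' Check that the tissue surfaces are geometrically nested
#'
#' Every vertex of an inner surface must lie inside (or within `tol` of) the
#' next outer surface.
#'
#' @param geometry a [head_geometry()].
#' @param tol allowed protrusion (mm); defaults to the voxel pitch, the
#'   resolution at which rasterized surfaces are defined.
#' @return `TRUE` invisibly, or an error naming the offending pair.
#' @export
check_nesting <- function(geometry, tol = geometry$voxel_pitch) {
  ss <- geometry$surfaces
  for (i in seq_len(length(ss) - 1)) {
    inner <- ss[[i]]; outer <- ss[[i + 1]]
    v <- inner$vertices
    ok <- surface_contains(outer, v, tol = tol)
    if (!all(ok)) {
      bad <- v[!ok, , drop = FALSE]
      d <- nearest_surface_point(outer, bad[seq_len(min(50, nrow(bad))), ,
                                            drop = FALSE])$dist
      if (any(d > tol))
        stop(sprintf(
          "geometry error: surface '%s' protrudes from '%s' by up to %.3f mm",
          inner$name, outer$name, max(d)
        ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Layered spherical head phantom
#'
#' Concentric sphere surfaces standing in for white matter, gray matter and
#' CSF. The gray sphere has no sulci, so the closed-gray surface coincides
#' with it.
#'
#' @param radii_mm named, strictly increasing radii inner to outer; defaults
#'   to `c(white = 60, gray = 70, csf = 72)`.
#' @param mesh_edge_mm target triangle edge length (mm).
#' @param center sphere centre.
#' @param voxel_pitch voxel size (mm) carried for morphological operations.
#' @return a [head_geometry()] with surfaces white, gray, closed_gray, csf.
#' @export
make_layered_sphere_head <- function(radii_mm = c(white = 60, gray = 70, csf = 72),
                                     mesh_edge_mm = 3, center = c(0, 0, 0),
                                     voxel_pitch = 1) {
  if (any(diff(radii_mm) <= 0))
    stop("geometry error: radii must be strictly increasing inner to outer",
         call. = FALSE)
  if (mesh_edge_mm <= 0)
    stop("geometry error: mesh_edge_mm must be positive", call. = FALSE)
  nm <- names(radii_mm)
  if (is.null(nm)) nm <- c("white", "gray", "csf")[seq_along(radii_mm)]
  surfaces <- list()
  for (i in seq_along(radii_mm)) {
    surfaces[[nm[i]]] <- icosphere(radii_mm[i], center, mesh_edge_mm, name = nm[i])
    if (nm[i] == "gray") {
      cg <- icosphere(radii_mm[i], center, mesh_edge_mm, name = "closed_gray")
      surfaces[["closed_gray"]] <- cg
    }
  }
  head_geometry(surfaces, voxel_pitch = voxel_pitch)
}

#' Layered slab head phantom
#'
#' A flat cortical patch: white matter below gray matter with a planar top at
#' `z = 0`. Used as the substrate for FEM verification and the CSF-depth
#' experiments, where curvature is not the property under test.
#'
#' @param extent_mm lateral size `c(Lx, Ly)`, centred on the origin.
#' @param gray_thickness_mm,white_thickness_mm layer thicknesses.
#' @param nx,ny top-surface grid resolution.
#' @param voxel_pitch voxel size (mm).
#' @return a [head_geometry()] with surfaces white, gray, closed_gray.
#' @export
make_layered_slab_head <- function(extent_mm = c(120, 120),
                                   gray_thickness_mm = 20,
                                   white_thickness_mm = 20,
                                   nx = 24, ny = 24, voxel_pitch = 1) {
  xl <- c(-1, 1) * extent_mm[1] / 2
  yl <- c(-1, 1) * extent_mm[2] / 2
  zg <- -gray_thickness_mm
  zw <- zg - white_thickness_mm
  white <- slab_surface(xl, yl, zw, zg, nx, ny, name = "white")
  gray <- slab_surface(xl, yl, zw, 0, nx, ny, name = "gray")
  cg <- slab_surface(xl, yl, zw, 0, nx, ny, name = "closed_gray")
  head_geometry(list(white = white, gray = gray, closed_gray = cg),
                voxel_pitch = voxel_pitch)
}

#' Gyral slab phantom with sinusoidal sulci
#'
#' A gray-matter slab whose top carries `n_gyri` parallel sulcal grooves of
#' the given depth and width, so the morphological closing filter has sulci
#' to fill. The closed-gray surface is computed honestly by
#' [close_surface()] on the rasterized phantom, and CSF by outward dilation.
#'
#' @param n_gyri number of sulcal grooves.
#' @param sulcus_depth_mm groove depth (mm); 0 gives a smooth slab.
#' @param sulcus_width_mm groove width at the top (mm).
#' @param extent_mm lateral patch size (square, mm).
#' @param thickness_mm slab thickness (mm).
#' @param csf_depth_mm outward dilation of the closed surface into CSF.
#' @param closing_radius_mm structuring radius for the closing filter;
#'   defaults to the sulcus width (enough to bridge the grooves).
#' @param voxel_pitch voxel size (mm).
#' @return a [head_geometry()] with surfaces gray, closed_gray, csf.
#' @export
make_gyral_phantom <- function(n_gyri = 4, sulcus_depth_mm = 10,
                               sulcus_width_mm = 3, extent_mm = 60,
                               thickness_mm = 25, csf_depth_mm = 2,
                               closing_radius_mm = sulcus_width_mm,
                               voxel_pitch = 1) {
  if (sulcus_width_mm <= 0)
    stop("geometry error: sulcus_width_mm must be positive", call. = FALSE)
  if (sulcus_depth_mm < 0)
    stop("geometry error: sulcus_depth_mm must be non-negative", call. = FALSE)
  if (sulcus_depth_mm >= thickness_mm)
    stop("geometry error: sulcus depth exceeds slab thickness", call. = FALSE)
  L <- extent_mm
  xl <- c(-L / 2, L / 2); yl <- xl
  # groove centres, evenly spaced, away from the slab rim
  centers <- if (n_gyri > 0)
    seq(-L / 2 + L / (n_gyri + 1), L / 2 - L / (n_gyri + 1),
        length.out = n_gyri) else numeric(0)
  w <- sulcus_width_mm
  dep <- sulcus_depth_mm
  topf <- function(x, y) {
    z <- rep(0, length(x))
    # grooves end inside the patch (real sulci do not cut the rim): full
    # depth over the central span, cosine taper to zero near the rim
    ay <- abs(y) / (L / 2)
    taper <- ifelse(ay < 0.7, 1, ifelse(ay > 0.9, 0,
                                        0.5 * (1 + cos(pi * (ay - 0.7) / 0.2))))
    for (cx in centers) {
      u <- (x - cx) / (w / 2)
      mask <- abs(u) < 1
      # cosine-profiled groove: depth `dep`, width `w` at the top
      z[mask] <- z[mask] - dep * taper[mask] * 0.5 * (1 + cos(pi * u[mask]))
    }
    z - 1e-6   # keep strictly below z = 0 so the flat-top test is clean
  }
  nx <- max(60L, ceiling(L / min(voxel_pitch, w / 4)))
  gray <- if (dep > 0) {
    slab_surface(xl, yl, -thickness_mm, topf, nx = nx, ny = max(30L, nx %/% 2),
                 name = "gray")
  } else {
    slab_surface(xl, yl, -thickness_mm, -1e-6, nx = 16, ny = 16, name = "gray")
  }
  cg <- close_surface(gray, closing_radius_mm, voxel_pitch)
  cg$name <- "closed_gray"
  csf <- dilate_surface(cg, csf_depth_mm, voxel_pitch)
  csf$name <- "csf"
  head_geometry(list(gray = gray, closed_gray = cg, csf = csf),
                voxel_pitch = voxel_pitch)
}

#' Morphological closing of a closed surface
#'
#' Rasterizes the surface at `voxel_pitch`, applies dilation-then-erosion
#' with a ball of `radius_mm`, and re-surfaces the closed mask. Grooves
#' narrower than twice the radius are filled; the result contains the input
#' up to rasterization.
#'
#' @param surface a closed [tri_surface()].
#' @param radius_mm structuring-element radius (mm).
#' @param voxel_pitch voxel size (mm); must not exceed the radius (a
#'   structuring element below the grid resolution does nothing).
#' @return a closed [tri_surface()] named `closed_<input>`.
#' @export
close_surface <- function(surface, radius_mm, voxel_pitch = 1) {
  if (!is_closed_surface(surface))
    stop("geometry error: close_surface requires a closed surface", call. = FALSE)
  if (radius_mm < 0)
    stop("geometry error: radius_mm must be non-negative", call. = FALSE)
  if (radius_mm > 0 && voxel_pitch > radius_mm)
    stop("geometry error: voxel_pitch must not exceed radius_mm", call. = FALSE)
  vg <- voxelize_surface(surface, voxel_pitch,
                         pad = ceiling(radius_mm / voxel_pitch) + 2L)
  vc <- voxel_close(vg, radius_mm)
  vc$grid <- vc$grid | vg$grid    # closing is extensive up to rasterization
  voxel_surface(vc, name = paste0("closed_", surface$name))
}

#' Outward dilation of a closed surface
#'
#' Voxel-based outward offset by `depth_mm`; immune to the self-intersection
#' problems of direct mesh offsetting at high curvature.
#'
#' @param surface a closed [tri_surface()].
#' @param depth_mm offset depth (mm).
#' @param voxel_pitch voxel size (mm).
#' @return a closed [tri_surface()] containing the input.
#' @export
dilate_surface <- function(surface, depth_mm, voxel_pitch = 1) {
  if (!is_closed_surface(surface))
    stop("geometry error: dilate_surface requires a closed surface", call. = FALSE)
  if (depth_mm < 0)
    stop("geometry error: depth_mm must be non-negative", call. = FALSE)
  vg <- voxelize_surface(surface, voxel_pitch,
                         pad = ceiling(depth_mm / voxel_pitch) + 2L)
  vd <- voxel_dilate(vg, depth_mm)
  vd$grid <- vd$grid | vg$grid
  voxel_surface(vd, name = paste0("dilated_", surface$name))
}
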