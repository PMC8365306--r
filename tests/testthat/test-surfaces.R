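# Triangulated surfaces, rasterization and the morphological closing that
# produces the closed gray matter surface.

test_that("icosphere is closed, outward-oriented and volumetrically accurate", {
  s <- icosphere(70, mesh_edge_mm = 3)
  expect_true(is_closed_surface(s))
  expect_equal(surface_volume(s), 4 / 3 * pi * 70^3, tolerance = 0.02)
  # vertices sit exactly on the sphere
  expect_lt(max(abs(sqrt(rowSums(s$vertices^2)) - 70)), 1e-9)
})

test_that("face index validation and closedness checks catch bad input", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_surface(v, rbind(c(1, 2, 4))), "out of range")
  open_tri <- tri_surface(v, rbind(c(1, 2, 3)))
  expect_false(is_closed_surface(open_tri))
  expect_error(close_surface(open_tri, 2), "closed")
  expect_error(dilate_surface(open_tri, 2), "closed")
})

test_that("ray casting, containment and nearest-point agree with the sphere", {
  s <- icosphere(40, mesh_edge_mm = 5)
  h <- first_ray_hit(s, rbind(c(0, 0, 0)), rbind(c(1, 0, 0)))
  expect_equal(h$t, 40, tolerance = 0.01)
  # generic parity path matches the analytic path
  s_generic <- s
  s_generic$analytic <- NULL
  set.seed(4)
  pts <- matrix(runif(240, -50, 50), 80, 3)
  expect_identical(surface_contains(s_generic, pts),
                   surface_contains(s, pts))
  np <- nearest_surface_point(s, rbind(c(60, 0, 0), c(0, 0, 5)))
  expect_equal(np$dist, c(20, 35), tolerance = 0.05)
})

test_that("layered sphere head is nested and rejects non-increasing radii", {
  h <- sphere_head()
  expect_named(h$surfaces, c("white", "gray", "closed_gray", "csf"))
  expect_true(check_nesting(h))
  expect_error(make_layered_sphere_head(c(white = 70, gray = 60)),
               "strictly increasing")
})

test_that("closing a convex surface is near-identity; dilation offsets it", {
  s <- icosphere(20, mesh_edge_mm = 4)
  closed <- close_surface(s, 3, voxel_pitch = 1)
  # a convex input is a fixed point of closing up to one voxel shell
  shell <- 4 * pi * 20^2 * 1
  expect_lt(abs(surface_volume(closed) - surface_volume(s)), shell)
  expect_true(is_closed_surface(closed))
  dil <- dilate_surface(s, 2, voxel_pitch = 1)
  r_eff <- (surface_volume(dil) * 3 / (4 * pi))^(1 / 3)
  expect_equal(r_eff, 22, tolerance = 0.05)
  # containment: input vertices inside the dilated surface
  expect_true(all(surface_contains(dil, s$vertices)))
  # zero radius / preconditions
  expect_error(close_surface(s, 2, voxel_pitch = 3), "voxel_pitch")
})

test_that("gyral phantom: closing fills the sulci and recovers the void volume", {
  g <- make_gyral_phantom(n_gyri = 4, sulcus_depth_mm = 10,
                          sulcus_width_mm = 3, extent_mm = 60)
  expect_true(check_nesting(g))
  vols <- vapply(g$surfaces, surface_volume, numeric(1))
  expect_gt(vols[["closed_gray"]], vols[["gray"]])
  # voxel-count oracle: flat-capped slab minus the grooved gray mask
  flat <- slab_surface(c(-30, 30), c(-30, 30), -25, -1e-6, 16, 16)
  void_vox <- voxel_volume(voxelize_surface(flat, 1)) -
    voxel_volume(voxelize_surface(g$surfaces$gray, 1))
  recovered <- voxel_volume(voxelize_surface(g$surfaces$closed_gray, 1)) -
    voxel_volume(voxelize_surface(g$surfaces$gray, 1))
  expect_equal(recovered, void_vox, tolerance = 0.15)
  # depth-map oracle: no closed-surface point deeper than 1 voxel below the
  # gyral crowns, away from the rim
  a <- g$surfaces$closed_gray$analytic
  d <- dim(a$grid)
  zs <- a$origin[3] + (seq_len(d[3]) - 0.5) * a$pitch
  xs <- a$origin[1] + (seq_len(d[1]) - 0.5) * a$pitch
  ys <- a$origin[2] + (seq_len(d[2]) - 0.5) * a$pitch
  topz <- apply(a$grid, c(1, 2), function(col) if (any(col)) max(zs[col]) else NA)
  interior <- abs(xs) < 27
  interior_y <- abs(ys) < 27
  expect_gte(min(topz[interior, interior_y], na.rm = TRUE), -0.5 - 1)
})

test_that("zero sulcus depth yields a smooth slab that closing barely changes", {
  g <- make_gyral_phantom(n_gyri = 4, sulcus_depth_mm = 0,
                          sulcus_width_mm = 3, extent_mm = 40,
                          thickness_mm = 15)
  vols <- vapply(g$surfaces[c("gray", "closed_gray")], surface_volume, numeric(1))
  expect_equal(vols[["closed_gray"]], vols[["gray"]], tolerance = 0.01)
  expect_error(make_gyral_phantom(sulcus_depth_mm = 30, thickness_mm = 25),
               "exceeds")
  expect_error(make_gyral_phantom(sulcus_width_mm = 0), "positive")
})

test_that("closing volume is monotone non-decreasing in the radius", {
  g <- fixture("gyral_small", function() {
    make_gyral_phantom(n_gyri = 2, sulcus_depth_mm = 6, sulcus_width_mm = 4,
                       extent_mm = 40, thickness_mm = 15, csf_depth_mm = 1,
                       closing_radius_mm = 2)
  })
  vols <- vapply(c(1, 2, 3), function(r) {
    surface_volume(close_surface(g$surfaces$gray, r, voxel_pitch = 1))
  }, numeric(1))
  v_gray <- voxel_volume(voxelize_surface(g$surfaces$gray, 1))
  expect_true(all(diff(vols) >= 0))
  expect_true(all(vols >= v_gray - 1e-9))
})

test_that("surface PLY round-trip preserves geometry", {
  s <- icosphere(10, mesh_edge_mm = 5, name = "gray")
  p <- file.path(tempdir(), "s.ply")
  write_surface_ply(s, p)
  s2 <- read_surface_ply(p)
  expect_equal(s2$vertices, s$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(s2$faces, s$faces, ignore_attr = TRUE)
  expect_identical(s2$name, "gray")
})
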