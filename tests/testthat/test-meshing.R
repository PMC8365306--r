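# Electrode disks, insulating sheet, rigid-model clipping and the
# region-labelled tetrahedral mesher.

test_that("electrode disk: 73 nodes, exact radius, coplanar, rotation-equivariant", {
  d <- build_disk(c(1, 2, 3), c(0, 0, 1), 2.3, "A1")
  expect_identical(nrow(d$node_points), 73L)
  r <- sqrt(rowSums(sweep(d$node_points, 2, d$center)^2))
  expect_equal(max(r), 1.15)
  expect_true(all(r <= 1.15 + 1e-12))
  expect_equal(d$node_points[, 3], rep(3, 73))
  # rotation equivariance: rotating (center, normal) rotates all nodes
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  d0 <- build_disk(c(0, 0, 0), c(0, 0.6, 0.8))
  dr <- build_disk(c(0, 0, 0), as.numeric(R %*% c(0, 0.6, 0.8)))
  expect_lt(max(abs(dr$node_points - t(R %*% t(d0$node_points)))), 1e-9)
  expect_error(build_disk(c(0, 0, 0), c(0, 0, 0)), "non-zero")
  # coplanarity for an arbitrary normal
  n <- c(1, -2, 0.5) / sqrt(5.25)
  da <- build_disk(c(5, 5, 5), n)
  offs <- sweep(da$node_points, 2, da$center) %*% n
  expect_lt(max(abs(offs)), 1e-9)
})

test_that("planar sheet is a closed solid of the right thickness", {
  es <- apply_brain_shift(slab_grid(), shift_model(5, 0, seed = 1))
  cg <- slab_head()$surfaces$closed_gray
  hp <- hermes_project(es, cg)
  disks <- build_disks(hp, cg)
  sheet <- build_sheet(disks, cg, thickness_mm = 0.5)
  expect_true(is_closed_surface(sheet))
  zr <- range(sheet$vertices[, 3])
  expect_equal(diff(zr), 0.5)
  expect_equal(zr[1], 0)     # underside on the surface, disks embedded on it
})

test_that("spherical sheet drapes the cap with the underside on the sphere", {
  ess <- apply_brain_shift(sphere_grid(), shift_model(5, 0, "radial", seed = 1))
  cg <- sphere_head()$surfaces$closed_gray
  hp <- hermes_project(ess, cg)
  disks <- build_disks(hp, cg)
  sheet <- build_sheet(disks, cg, thickness_mm = 0.5)
  expect_true(is_closed_surface(sheet))
  rr <- sqrt(rowSums(sheet$vertices^2))
  expect_gte(min(rr), 80 - 0.05)
  expect_lte(max(rr), 80.5 + 0.05)
  inner <- rr < 80.25
  expect_equal(unname(rr[inner]), rep(80, sum(inner)), tolerance = 1e-3)
})

test_that("rigid clipping removes tissue above the electrode plane", {
  geom <- make_layered_slab_head(extent_mm = c(120, 120))
  es <- place_grid(geom, c(8, 8), 10)
  es <- apply_brain_shift(es, shift_model(3, 0, seed = 1))   # 3 mm inside
  clipped <- clip_gray_for_rigid(geom, es)
  cg <- clipped$surfaces$closed_gray
  expect_true(is_closed_surface(cg))
  # under the grid the new top passes through the electrode plane +- 1 voxel
  np <- nearest_surface_point(cg, es$rigid_centroids[c(1, 28, 64), , drop = FALSE])
  expect_lt(max(np$dist), 1.0)
  # outside the footprint the top remains at z = 0
  far <- surface_contains(cg, rbind(c(55, 55, -0.6)))
  expect_true(far)
  # electrodes already outside tissue: unchanged with a warning
  es_out <- es
  es_out$rigid_centroids <- es$true_centroids + cbind(0, 0, rep(5, 64))
  expect_warning(unchanged <- clip_gray_for_rigid(geom, es_out), "unchanged")
  expect_identical(names(unchanged$surfaces), names(geom$surfaces))
})

test_that("tetrahedral mesh partitions the phantom into positive, labelled regions", {
  geom <- make_layered_slab_head(extent_mm = c(80, 80), gray_thickness_mm = 10,
                                 white_thickness_mm = 10)
  sheet <- slab_surface(c(-20, 20), c(-20, 20), 0, 0.5, 4, 4, name = "sheet")
  csf <- NULL
  mesh <- tetrahedralize(geom, sheet = sheet,
                         sizing = list(h_fine = 4, h_coarse = 10,
                                       fine_xy = rbind(c(-25, 25), c(-25, 25))))
  v <- tet_volumes(mesh)
  expect_true(all(v > 0))
  expect_false(any(is.na(mesh$region)))
  rv <- region_volumes(mesh)
  expect_equal(sum(rv), sum(v))
  # region volumes within 3% of the construction volumes
  expect_equal(unname(rv["gray"]), 80 * 80 * 10, tolerance = 0.03)
  expect_equal(unname(rv["white"]), 80 * 80 * 10, tolerance = 0.03)
  expect_equal(unname(rv["silicone"]), 40 * 40 * 0.5, tolerance = 0.03)
})

test_that("halving the target edge length barely changes region volumes", {
  geom <- make_layered_slab_head(extent_mm = c(60, 60), gray_thickness_mm = 10,
                                 white_thickness_mm = 8)
  vols <- lapply(c(4, 2), function(h) {
    region_volumes(tetrahedralize(geom, sizing = list(h_fine = h, h_coarse = 8)))
  })
  expect_equal(vols[[1]][["gray"]], vols[[2]][["gray"]], tolerance = 0.01)
  expect_equal(vols[[1]][["white"]], vols[[2]][["white"]], tolerance = 0.01)
})

test_that("disk embedding yields unit-sum weights over mesh nodes", {
  geom <- make_layered_slab_head(extent_mm = c(80, 80), gray_thickness_mm = 10,
                                 white_thickness_mm = 8)
  es <- place_grid(geom, c(2, 2), 10)
  proj <- rigid_localize(es)
  disks <- build_disks(proj, geom$surfaces$closed_gray)
  mesh <- tetrahedralize(geom, disks = disks,
                         sizing = list(h_fine = 3, h_coarse = 8))
  W <- mesh$electrode_weights
  expect_identical(rownames(W), es$labels)
  expect_equal(unname(Matrix::rowSums(W)), rep(1, 4))
  expect_true(all(W@x >= 0))
  expect_true(all(lengths(mesh$electrode_nodes) > 0))
  # node sets are subsets of mesh nodes
  expect_true(all(unlist(mesh$electrode_nodes) <= nrow(mesh$nodes)))
})

test_that("mesh serializes to legacy VTK", {
  geom <- make_layered_slab_head(extent_mm = c(40, 40), gray_thickness_mm = 8,
                                 white_thickness_mm = 6)
  mesh <- tetrahedralize(geom, sizing = list(h_fine = 4, h_coarse = 8))
  p <- file.path(tempdir(), "mesh.vtk")
  write_mesh_vtk(mesh, p)
  lines <- readLines(p)
  expect_identical(lines[4], "DATASET UNSTRUCTURED_GRID")
  expect_true(any(grepl("^CELLS", lines)))
  expect_true(any(grepl("SCALARS region", lines)))
})
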