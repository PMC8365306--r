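# Electrode projection methods and brain-shift metrics.

test_that("rigid centroid is the artifact mean and needs >= 10 voxels", {
  cl <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
              c(0, 0, -1), c(0, 0, 1), c(-2, 0, 0), c(2, 0, 0),
              c(0, -2, 0), c(0, 2, 0))
  expect_equal(rigid_centroid(cl), c(0, 0, 0))
  expect_equal(rigid_centroid(cl + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)),
               c(1, 2, 3))
  expect_error(rigid_centroid(cl[1:5, ]), "10")
})

test_that("principal axis projects along the artifact axis to the surface", {
  plane <- slab_surface(c(-50, 50), c(-50, 50), -20, 10, 10, 10)
  # exactly collinear voxels along z below the z = 10 plane
  cloud <- cbind(0, 0, seq(-3, 3, length.out = 13))
  pr <- principal_axis_project(cloud, plane)
  expect_equal(pr$point, c(0, 0, 10), tolerance = 1e-9)
  expect_false(pr$fallback)
  # oblique elongated cloud: the hit equals the closed-form ray-plane
  # solution for the realized (estimated) axis through the centroid
  t1 <- c(sin(pi / 6), 0, cos(pi / 6))      # 30 degrees off the normal
  set.seed(9)
  loc <- cbind(rnorm(60, sd = 3), rnorm(60, sd = 0.3), rnorm(60, sd = 0.3))
  e1 <- c(cos(pi / 6), 0, -sin(pi / 6))
  e2 <- c(0, 1, 0)
  cloud2 <- loc[, 1] %o% t1 + loc[, 2] %o% e1 + loc[, 3] %o% e2
  cloud2 <- sweep(cloud2, 2, colMeans(cloud2))   # centred at origin
  pr2 <- principal_axis_project(cloud2, plane)
  dir <- pr2$direction * sign(pr2$direction[3])
  expected <- (10 / dir[3]) * dir
  expect_lt(sqrt(sum((pr2$point - expected)^2)), 0.01)
  expect_lt(acos(abs(sum(pr2$direction * t1))) * 180 / pi, 5)
  # an exactly isotropic cloud (cube corners + face centres) is degenerate
  iso <- rbind(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
               2 * rbind(diag(3), -diag(3)))
  expect_error(principal_axis_project(iso, plane, label = "C3"),
               "degenerate.*C3")
})

test_that("hermes stencil uses 4-neighbours plus diagonals only at corners", {
  st <- ecogvolt:::hermes_stencil(c(8, 8))
  expect_length(st[[10]], 4)                    # interior (B2)
  expect_length(st[[2]], 3)                     # edge (A2): 3 lateral
  expect_length(st[[1]], 3)                     # corner (A1): 2 lateral + 1 diagonal
  expect_setequal(st[[1]], c(2L, 9L, 10L))
  expect_error(hermes_project(place_grid(slab_head(), c(1, 6), 10),
                              slab_head()$surfaces$closed_gray), NA)
})

test_that("parallel planar shift: all three methods recover the foot points", {
  es <- apply_brain_shift(slab_grid(), shift_model(5, 0, seed = 1))
  cg <- slab_head()$surfaces$closed_gray
  hp <- hermes_project(es, cg)
  expect_lt(max_dist(hp$projected_centroids, es$true_centroids), 1e-6)
  expect_equal(as.vector(projection_distances(hp)), rep(5, 64))
  # exactly axial artifact clouds so the parallel-plane property is exact
  es$artifacts <- lapply(seq_along(es$labels), function(i) {
    sweep(cbind(0, 0, seq(-2, 2, length.out = 15)), 2,
          es$rigid_centroids[i, ], "+")
  })
  names(es$artifacts) <- es$labels
  pa <- project_electrodes(es, cg, "principal_axis")
  expect_lt(max_dist(pa$projected_centroids, es$true_centroids), 1e-6)
  dk <- dykstra_project(es, cg)
  expect_lt(max_dist(dk$projected_centroids, es$true_centroids), 1e-6)
  expect_true(dk$converged)
  # at the constrained optimum the deformation term vanishes: E = n * shift^2
  e_final <- utils::tail(dk$objective_trace, 1)
  expect_equal(e_final, 64 * 25, tolerance = 1e-6)
})

test_that("dykstra on already-on-surface input returns E = 0 in 0 iterations", {
  es <- slab_grid()   # rigid = true, on the surface
  dk <- dykstra_project(es, slab_head()$surfaces$closed_gray)
  expect_identical(dk$iterations, 0L)
  expect_identical(dk$projected_centroids, es$rigid_centroids)
  expect_equal(dk$objective_trace, 0)
  expect_equal(as.vector(projection_distances(dk)), rep(0, 64))
})

test_that("rigid localization keeps centroids and reports zero distances", {
  es <- apply_brain_shift(slab_grid(), shift_model(4, 1, seed = 2))
  rl <- rigid_localize(es)
  expect_identical(rl$projected_centroids, es$rigid_centroids)
  expect_equal(as.vector(projection_distances(rl)), rep(0, 64))
  d <- inter_electrode_distances(rl, es$adjacency)
  d0 <- sqrt(rowSums((es$rigid_centroids[es$adjacency[, 1], ] -
                        es$rigid_centroids[es$adjacency[, 2], ])^2))
  expect_equal(unname(d), d0)
})

test_that("csf offset moves contacts along the surface normal", {
  es <- apply_brain_shift(slab_grid(), shift_model(5, 0, seed = 1))
  cg <- slab_head()$surfaces$closed_gray
  hp <- hermes_project(es, cg)
  expect_identical(offset_csf(hp, cg, 0)$projected_centroids,
                   hp$projected_centroids)
  o1 <- offset_csf(hp, cg, 1)
  expect_equal(o1$projected_centroids[, 3], rep(1, 64))
  expect_error(offset_csf(hp, cg, -1), ">= 0")
  # sphere: depth 2 puts centroids at radius 82 within 0.05 mm
  ess <- apply_brain_shift(sphere_grid(), shift_model(5, 0, "radial", seed = 1))
  hps <- hermes_project(ess, sphere_head()$surfaces$closed_gray)
  o2 <- offset_csf(hps, sphere_head()$surfaces$closed_gray, 2)
  expect_equal(sqrt(rowSums(o2$projected_centroids^2)), rep(82, 64),
               tolerance = 0.05 / 82)
})

test_that("projection and inter-electrode distances match brute force", {
  es <- apply_brain_shift(slab_grid(), shift_model(4, 1, seed = 31))
  cg <- slab_head()$surfaces$closed_gray
  hp <- hermes_project(es, cg)
  expect_equal(as.vector(projection_distances(hp)),
               sqrt(rowSums((hp$projected_centroids - es$rigid_centroids)^2)))
  d <- inter_electrode_distances(hp, es$adjacency)
  brute <- apply(es$adjacency, 1, function(ij) {
    sqrt(sum((hp$projected_centroids[ij[1], ] -
                hp$projected_centroids[ij[2], ])^2))
  })
  expect_equal(unname(d), brute)
  s <- attr(projection_distances(hp), "summary")
  expect_named(s, c("median", "q1", "q3"))
})

test_that("all methods land contacts on the closed-gray surface", {
  es <- apply_brain_shift(sphere_grid(), shift_model(5, 1, "radial", seed = 7))
  es <- synthesize_artifacts(es, -es$normals, elongation = 4, seed = 8)
  cg <- sphere_head()$surfaces$closed_gray
  for (m in c("hermes", "principal_axis", "dykstra")) {
    pr <- project_electrodes(es, cg, m)
    np <- nearest_surface_point(cg, pr$projected_centroids)
    expect_lt(max(np$dist), 0.1)
  }
})

test_that("projection TSV serialization round-trips the key columns", {
  es <- apply_brain_shift(slab_grid(), shift_model(3, 0, seed = 1))
  hp <- hermes_project(es, slab_head()$surfaces$closed_gray)
  p <- file.path(tempdir(), "proj.tsv")
  write_projection_tsv(hp, p, csf_depth_mm = 1, seed = 42)
  df <- utils::read.delim(p)
  expect_identical(nrow(df), 64L)
  expect_equal(df$distance_mm, unname(hp$projection_distances))
  man <- yaml::read_yaml(paste0(p, ".manifest.yaml"))
  expect_identical(man$method, "hermes")
  expect_identical(man$csf_depth_mm, 1)
})
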