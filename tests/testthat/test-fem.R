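# Poisson volume-conduction solver: assembly oracles, load compatibility,
# gauge, linearity, reciprocity and the analytic half-space checks.

# independent single-element oracle: gradients via base-R solve()
element_stiffness_oracle <- function(V, sigma) {
  J <- cbind(V[2, ] - V[1, ], V[3, ] - V[1, ], V[4, ] - V[1, ])
  vol <- abs(det(J)) / 6
  Ginv <- solve(J)
  G <- rbind(-colSums(Ginv), Ginv)    # rows: grad lambda_1..4 (as row vectors)
  sigma * vol * G %*% t(G)
}

single_tet_mesh <- function(V) {
  tet_mesh(V, matrix(1:4, 1), "gray")
}

test_that("element stiffness matches an independently assembled 4x4 matrix", {
  # regular tetrahedron, unit edge
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
             c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  K <- as.matrix(assemble(single_tet_mesh(V), c(gray = 1)))
  expect_equal(unname(K), unname(element_stiffness_oracle(V, 1)),
               tolerance = 1e-12)
  expect_equal(rowSums(K), rep(0, 4), tolerance = 1e-12)
  # an irregular element too (oracle computed in element-vertex order,
  # mapped back to node order)
  set.seed(11)
  V2 <- matrix(rnorm(12), 4, 3)
  m2 <- single_tet_mesh(V2)
  if (tet_volumes(m2) < 0) m2$tets <- m2$tets[, c(1, 2, 4, 3), drop = FALSE]
  K2 <- as.matrix(assemble(m2, c(gray = 0.33)))
  perm <- m2$tets[1, ]
  Ko <- matrix(0, 4, 4)
  Ko[perm, perm] <- element_stiffness_oracle(m2$nodes[perm, ], 0.33)
  expect_equal(unname(K2), unname(Ko), tolerance = 1e-10)
})

test_that("assembly is linear in sigma, symmetric, and names missing regions", {
  geom <- make_layered_slab_head(extent_mm = c(40, 40), gray_thickness_mm = 8,
                                 white_thickness_mm = 6)
  mesh <- tetrahedralize(geom, sizing = list(h_fine = 4, h_coarse = 8))
  K1 <- assemble(mesh, c(gray = 0.33, white = 0.142))
  K2 <- assemble(mesh, c(gray = 0.66, white = 0.142))
  Kg <- assemble(mesh, c(gray = 0.33, white = 1e-30))
  expect_lt(max(abs(K2 - K1 - Kg * (1 - 1e-30 / 0.33))), 1e-10)
  expect_equal(max(abs(K1 - Matrix::t(K1))), 0)
  expect_lt(max(abs(Matrix::rowSums(K1))), 1e-12)
  expect_error(assemble(mesh, c(gray = 0.33)), "white")
})

test_that("solver handles trivial loads, scales linearly, enforces the gauge", {
  geom <- make_layered_slab_head(extent_mm = c(60, 60), gray_thickness_mm = 10,
                                 white_thickness_mm = 8)
  mesh <- tetrahedralize(geom, sizing = list(h_fine = 3, h_coarse = 8))
  K <- assemble(mesh, conductivity_table())
  sol0 <- solve_fem(K, numeric(nrow(mesh$nodes)))
  expect_identical(sol0$v, numeric(nrow(mesh$nodes)))
  rhs <- point_source_rhs(mesh, c(10, 0, 0), c(-10, 0, 0), 1)
  expect_identical(sum(rhs), 0)
  s1 <- solve_fem(K, rhs)
  s2 <- solve_fem(K, 2 * rhs)
  expect_equal(s2$v, 2 * s1$v, tolerance = 1e-12)
  expect_lt(abs(mean(s1$v)), 1e-12 * max(abs(s1$v)))
  expect_lte(s1$residual, 1e-8)
  # incompatible load is rejected
  bad <- rhs; bad[1] <- bad[1] + 0.5
  expect_error(solve_fem(K, bad), "sum to zero")
})

test_that("superposition of two bipolar pairs equals the sum of solutions", {
  geom <- make_layered_slab_head(extent_mm = c(60, 60), gray_thickness_mm = 10,
                                 white_thickness_mm = 8)
  mesh <- tetrahedralize(geom, sizing = list(h_fine = 3, h_coarse = 8))
  K <- assemble(mesh, conductivity_table())
  r1 <- point_source_rhs(mesh, c(9, 0, 0), c(-9, 0, 0), 1)
  r2 <- point_source_rhs(mesh, c(0, 9, 0), c(0, -9, 0), 2)
  va <- solve_fem(K, r1)$v + solve_fem(K, r2)$v
  vb <- solve_fem(K, r1 + r2)$v
  expect_equal(vb, va, tolerance = 1e-6)
})

test_that("electrode voltages average the disk nodes and respect symmetry", {
  geom <- make_layered_slab_head(extent_mm = c(100, 100),
                                 gray_thickness_mm = 15,
                                 white_thickness_mm = 10)
  es <- place_grid(geom, c(1, 4), 10)
  proj <- rigid_localize(es)
  disks <- build_disks(proj, geom$surfaces$closed_gray)
  mesh <- tetrahedralize(geom, disks = disks,
                         sizing = list(h_fine = 2.5, h_coarse = 10))
  K <- assemble(mesh, conductivity_table())
  stim <- stim_config("A2", "A3", amplitude_mA = 1)
  rhs <- make_rhs(mesh, stim)
  expect_equal(sum(rhs), 0, tolerance = 1e-15)
  expect_equal(sum(abs(rhs)), 2, tolerance = 1e-12)   # sum |rhs| = 2 * I0
  sol <- solve_fem(K, rhs)
  v <- electrode_voltage(sol, mesh, c("A1", "A2", "A3", "A4"))
  # uniform-field sanity: mean-weight sampling reproduces a constant field
  const <- structure(list(v = rep(3.2, nrow(mesh$nodes))), class = "nodal_solution")
  expect_equal(unname(electrode_voltage(const, mesh, "A1")), 3.2)
  # antisymmetric pair: outer electrodes see equal and opposite voltages
  expect_equal(v[["A1"]], -v[["A4"]], tolerance = abs(v[["A4"]]) * 0.01)
  expect_equal(v[["A2"]], -v[["A3"]], tolerance = abs(v[["A3"]]) * 0.01)
  # matches direct weight averaging
  expect_equal(unname(v["A1"]),
               as.numeric(mesh$electrode_weights["A1", ] %*% sol$v))
  expect_error(electrode_voltage(sol, mesh, "Z9"), "unknown")
})

test_that("analytic half-space formula: values, symmetry, antisymmetry", {
  v10 <- analytic_half_space(1, 0.33, c(0, 0, 0), NULL, rbind(c(10, 0, 0)))
  expect_equal(v10, 1 / (2 * pi * 0.33 * 10))          # 48.23 mV
  expect_equal(v10 * 1000, 48.23, tolerance = 1e-4)
  # equidistant query from source and sink is at zero potential
  v0 <- analytic_half_space(1, 0.33, c(5, 0, 0), c(-5, 0, 0), rbind(c(0, 7, 0)))
  expect_equal(v0, 0)
  # swapping source and sink negates the field
  q <- rbind(c(12, 3, 0), c(-4, 8, 0))
  expect_equal(analytic_half_space(1, 0.33, c(5, 0, 0), c(-5, 0, 0), q),
               -analytic_half_space(1, 0.33, c(-5, 0, 0), c(5, 0, 0), q))
  expect_error(analytic_half_space(1, 0.33, c(0, 0, 0), NULL, rbind(c(0, 0, 0))),
               "coincides")
})

test_that("conductivity table carries the literature values", {
  tab <- conductivity_table()
  expect_equal(tab[["gray"]], 0.330)
  expect_equal(tab[["white"]], 0.142)
  expect_equal(tab[["csf"]], 1.790)
  expect_equal(tab[["ventricles"]], 1.790)
  expect_equal(tab[["silicone"]], 1e-10)
  expect_error(conductivity_table(gray = -1), "positive")
})
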