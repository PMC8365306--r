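#!/usr/bin/env Rscript
# Solver verification against the analytic half-space solution: a uniform
# gray slab with a 1 mA bipolar pair 10 mm apart on the insulating top
# face, sampled 5-30 mm from the nearer monopole, over three mesh
# refinements; plus reciprocity and amplitude linearity.
#
# Outputs under results/fem/.

suppressPackageStartupMessages(library(ecogvolt))
out <- "results/fem"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gray <- slab_surface(c(-120, 120), c(-120, 120), -80, 0, 8, 8, name = "gray")
geom <- head_geometry(list(gray = gray))

rows <- lapply(c(5, 2.5, 1.25), function(h) {
  t0 <- Sys.time()
  mesh <- tetrahedralize(geom, sizing = list(
    h_fine = h, h_coarse = 20, growth = 1.7,
    fine_xy = rbind(c(-45, 45), c(-10, 10))
  ))
  K <- assemble(mesh, c(gray = 0.330))
  sol <- solve_fem(K, point_source_rhs(mesh, c(5, 0, 0), c(-5, 0, 0), 1),
                   tol = 1e-8)
  xq <- seq(10, 35, by = 5)
  idx <- vapply(xq, function(x) nearest_node(mesh, c(x, 0, 0)), integer(1))
  vana <- analytic_half_space(1, 0.330, c(5, 0, 0), c(-5, 0, 0),
                              mesh$nodes[idx, , drop = FALSE])
  rel <- abs(sol$v[idx] - vana) / abs(vana)
  data.frame(h_mm = h, nodes = nrow(mesh$nodes), tets = nrow(mesh$tets),
             cg_iterations = sol$iterations,
             max_rel_err_pct = 100 * max(rel),
             mean_rel_err_pct = 100 * mean(rel),
             seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 1))
})
conv <- do.call(rbind, rows)
write.table(conv, file.path(out, "halfspace_convergence.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Half-space oracle convergence (error vs 2-monopole image solution):")
print(conv, row.names = FALSE)

## -- reciprocity and linearity on a small electrode model ------------------
geom2 <- make_layered_slab_head(extent_mm = c(100, 100),
                                gray_thickness_mm = 15,
                                white_thickness_mm = 10)
es <- place_grid(geom2, c(2, 3), 10)
disks <- build_disks(rigid_localize(es), geom2$surfaces$closed_gray)
mesh2 <- tetrahedralize(geom2, disks = disks,
                        sizing = list(h_fine = 2.5, h_coarse = 10))
K2 <- assemble(mesh2, conductivity_table())
W <- mesh2$electrode_weights
wa <- as.numeric(W["A1", ]); wb <- as.numeric(W["B3", ])
wr <- as.numeric(W["A3", ])
v_ab <- sum((wb - wr) * solve_fem(K2, wa - wr, tol = 1e-10)$v)
v_ba <- sum((wa - wr) * solve_fem(K2, wb - wr, tol = 1e-10)$v)
message(sprintf("Reciprocity: V(A->B) = %.6e V, V(B->A) = %.6e V, rel diff %.2e",
                v_ab, v_ba, abs(v_ab - v_ba) / abs(v_ab)))
s1 <- solve_fem(K2, 0.75 * (wa - wr), tol = 1e-10)$v
s2 <- solve_fem(K2, 1.50 * (wa - wr), tol = 1e-10)$v
message(sprintf("Linearity: max |V(2 I0) - 2 V(I0)| / max |V| = %.2e",
                max(abs(s2 - 2 * s1)) / max(abs(s2))))
writeLines(c(
  sprintf("reciprocity_rel_diff\t%.6e", abs(v_ab - v_ba) / abs(v_ab)),
  sprintf("linearity_rel_dev\t%.6e", max(abs(s2 - 2 * s1)) / max(abs(s2)))
), file.path(out, "reciprocity_linearity.tsv"))
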