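# Grid placement, simulated brain shift and CT-like artifact synthesis.

test_that("planar 8x8 grid has exact 10 mm pitch and 112 lattice pairs", {
  es <- slab_grid()
  expect_length(es$labels, 64)
  expect_identical(nrow(es$adjacency), 112L)   # 2 * 8 * 7
  d <- sqrt(rowSums((es$true_centroids[es$adjacency[, 1], ] -
                       es$true_centroids[es$adjacency[, 2], ])^2))
  expect_equal(d, rep(10, 112))
  expect_identical(es$labels[1:9], c(paste0("A", 1:8), "B1"))
})

test_that("spherical grid keeps every lattice edge at the exact geodesic chord", {
  es <- sphere_grid()
  chord <- 2 * 80 * sin(10 / (2 * 80))
  d <- sqrt(rowSums((es$true_centroids[es$adjacency[, 1], ] -
                       es$true_centroids[es$adjacency[, 2], ])^2))
  expect_equal(d, rep(chord, 112), tolerance = 1e-9)
  expect_equal(chord, 9.993491, tolerance = 1e-6)
  # centroids on the closed-gray sphere
  expect_lt(max(abs(sqrt(rowSums(es$true_centroids^2)) - 80)), 1e-9)
  # geodesic spacing within 2% of the pitch
  expect_equal(d / 10, rep(1, 112), tolerance = 0.02)
})

test_that("strips and oversized grids are handled", {
  st <- place_grid(slab_head(), c(1, 6), 10)
  expect_length(st$labels, 6)
  expect_identical(nrow(st$adjacency), 5L)
  expect_error(place_grid(slab_head(), c(20, 20), 10), "exceeds")
})

test_that("brain shift: identity, uniform magnitude, jitter recovery, determinism", {
  es <- slab_grid()
  es0 <- apply_brain_shift(es, shift_model(0, 0, seed = 1))
  expect_identical(es0$rigid_centroids, es0$true_centroids)
  es5 <- apply_brain_shift(es, shift_model(5, 0, seed = 1))
  d <- sqrt(rowSums((es5$rigid_centroids - es5$true_centroids)^2))
  expect_equal(d, rep(5, 64))
  # ground truth retained; jittered displacement within 3 * jitter_sd of the
  # configured magnitude
  esj <- apply_brain_shift(es, shift_model(5, 1, seed = 17))
  dj <- sqrt(rowSums((esj$rigid_centroids - esj$true_centroids)^2))
  expect_true(all(abs(dj - 5) < 3 * sqrt(3) * 1))
  esj2 <- apply_brain_shift(es, shift_model(5, 1, seed = 17))
  expect_identical(esj2$rigid_centroids, esj$rigid_centroids)
  expect_error(shift_model(-1), ">= 0")
})

test_that("synthesized artifacts have the requested axis and exact centroid", {
  es <- apply_brain_shift(slab_grid(), shift_model(4, 0.5, seed = 3))
  esa <- synthesize_artifacts(es, c(0, 0, 1), elongation = 4, n_voxels = 60,
                              seed = 5)
  for (lab in c("A1", "D4", "H8")) {
    cl <- esa$artifacts[[lab]]
    i <- match(lab, esa$labels)
    expect_lt(max_dist(rbind(colMeans(cl)), rbind(esa$rigid_centroids[i, ])),
              0.05)
    ev <- eigen(cov(cl), symmetric = TRUE)
    ang <- acos(min(1, abs(ev$vectors[3, 1]))) * 180 / pi
    expect_lt(ang, 5)
  }
  expect_error(synthesize_artifacts(es, c(0, 0, 1), elongation = 0.9),
               "elongation")
  # near-isotropic clouds are accepted here; the principal-axis projection
  # is the stage that must flag them as degenerate
  es_iso <- synthesize_artifacts(es, c(0, 0, 1), elongation = 1.01,
                                 n_voxels = 2000, seed = 13)
  plane <- slab_head()$surfaces$closed_gray
  expect_error(project_electrodes(es_iso, plane, "principal_axis"),
               "degenerate")
  expect_error(synthesize_artifacts(es, c(0, 0, 1), n_voxels = 9), "10")
})

test_that("recording synthesis is deterministic and rejects bad configurations", {
  pl <- c(A1 = 0.01, A2 = -0.005)
  r1 <- synthesize_recording(pl, n_pulses = 5, noise_sd = 1e-3, seed = 9)
  r2 <- synthesize_recording(pl, n_pulses = 5, noise_sd = 1e-3, seed = 9)
  expect_identical(r1$samples, r2$samples)
  expect_identical(samples_per_phase(r1), 14L)   # floor(0.0012 * 12207)
  expect_error(synthesize_recording(pl, n_pulses = 0), "n_pulses")
  expect_error(synthesize_recording(pl, sampling_rate = 5000), "8")
  expect_error(synthesize_recording(pl, pre_gap_ms = 30), "50 ms")
  # noiseless pulses are exact rectangles
  r0 <- synthesize_recording(pl, n_pulses = 3, noise_sd = 0, seed = 1)
  on <- r0$pulse_onsets[2]
  expect_equal(unname(r0$samples["A1", on:(on + 13)]), rep(0.01, 14))
  expect_equal(unname(r0$samples["A1", (on + 14):(on + 27)]), rep(-0.01, 14))
  # 10,005-pulse trains are a legal configuration (onset bookkeeping only)
  expect_silent(pulse_recording(matrix(0, 1, 7.7e6), 12207,
                                pulse_onsets = 700 + (0:10004) * 765))
})

test_that("recording round-trips through the raw-array container", {
  pl <- c(A1 = 0.02, B1 = -0.01)
  r <- synthesize_recording(pl, n_pulses = 3, noise_sd = 1e-4, seed = 2,
                            stim_pair = c("B4", "B3"))
  stem <- file.path(tempdir(), "rec")
  write_recording(r, stem)
  r2 <- read_recording(stem)
  expect_equal(r2$samples, r$samples)
  expect_identical(r2$pulse_onsets, r$pulse_onsets)
  expect_identical(r2$stim_pair, r$stim_pair)
})
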