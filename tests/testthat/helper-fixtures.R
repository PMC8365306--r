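# Shared fixtures, built once per test run. The spherical head and its
# placed grid are reused by the localization and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

sphere_head <- function() fixture("sphere_head", function() {
  make_layered_sphere_head(c(white = 70, gray = 80, csf = 82), mesh_edge_mm = 3)
})

sphere_grid <- function() fixture("sphere_grid", function() {
  place_grid(sphere_head(), c(8, 8), 10)
})

slab_head <- function() fixture("slab_head", function() {
  make_layered_slab_head(extent_mm = c(160, 160))
})

slab_grid <- function() fixture("slab_grid", function() {
  place_grid(slab_head(), c(8, 8), 10)
})

# maximum deviation between two point sets (rows)
max_dist <- function(a, b) max(sqrt(rowSums((a - b)^2)))

# inward artifact axes with angular wobble (CT streak direction noise)
artifact_axes_for_test <- function(electrodes, sd_deg, seed) {
  ax <- -electrodes$normals
  set.seed(seed)
  pert <- matrix(rnorm(3 * nrow(ax), sd = tan(sd_deg * pi / 180)), nrow(ax), 3)
  pert <- pert - rowSums(pert * ax) * ax
  u <- ax + pert
  u / sqrt(rowSums(u^2))
}
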