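# Shared fixtures: all phantoms are generated in code; noiseless variants
# cache across test files.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, maker) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- maker()
  .fixture_cache[[key]]
}

cyl_phantom <- function(r = 5, noise = 0, seed = 1, grid = 64) {
  fixture(sprintf("cyl_%g_%g_%d_%d", r, noise, seed, grid), function()
    render_phantom(phantom_spec("straight_tube", tube_radius_mm = r,
                                noise_sigma_hu = noise, seed = seed,
                                grid_shape = rep(grid, 3))))
}

arch_phantom <- function(r = 4, noise = 0, seed = 2, grid = 64) {
  fixture(sprintf("arch_%g_%g_%d_%d", r, noise, seed, grid), function()
    render_phantom(phantom_spec("torus_arch", tube_radius_mm = r,
                                noise_sigma_hu = noise, seed = seed,
                                grid_shape = rep(grid, 3))))
}

tree_phantom <- function(r = 4, noise = 0, seed = 3, grid = 64) {
  fixture(sprintf("tree_%g_%g_%d_%d", r, noise, seed, grid), function()
    render_phantom(phantom_spec("bifurcating_tree", tube_radius_mm = r,
                                noise_sigma_hu = noise, seed = seed,
                                grid_shape = rep(grid, 3))))
}

# RMS distance of centerline points from the z-parallel axis through (ax, ay)
rms_off_axis <- function(cl, ax = 31.5, ay = 31.5) {
  sqrt(mean((cl$points[, 1] - ax)^2 + (cl$points[, 2] - ay)^2))
}
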