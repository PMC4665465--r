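# Shared scene builders for the test suite. Simulations are cached per
# session so several test files can reuse the same fixture without
# re-rendering it.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(preset, noise = FALSE, seed = 1L) {
  key <- paste(preset, noise, seed, sep = "_")
  got <- .sim_cache[[key]]
  if (!is.null(got)) return(got)
  v <- simulate_run(fixture_spec(preset, seed = seed, noise = noise))
  .sim_cache[[key]] <- v
  v
}

# A small turbid phantom scene with one source, for cheap unit tests.
small_scene <- function(pos = c(5, 0, 0), power = 1e9) {
  ph <- build_cylinder_phantom(30, 40, 1)
  scene_model(point_source(pos, power), medium_registry("intralipid_1pct_560nm"),
              mesh = ph$mesh, grid = ph$grid, mask = ph$mask)
}

lipid <- function() medium_registry("intralipid_1pct_560nm")

# Random interior position for the 30 mm phantom, at least `margin` mm from
# the side wall and inside the cropped reconstruction grid axially.
random_interior_position <- function(margin = 3, zmax = 10) {
  repeat {
    p <- c(stats::runif(2, -(15 - margin), 15 - margin),
           stats::runif(1, -zmax, zmax))
    if (sqrt(sum(p[1:2]^2)) <= 15 - margin) return(p)
  }
}
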