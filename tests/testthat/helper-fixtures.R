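# Shared fixtures, built once per test run.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, build(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

flat_mesh <- function() {
  cached("flat", function() build_synthetic_roi(600, 0, 10, 20, seed = 11))
}

flat_gd <- function() {
  cached("flat_gd", function() geodesic_distance_matrix(flat_mesh()))
}

folded_mesh <- function() {
  cached("folded", function() build_synthetic_roi(900, 7, 24, 20, seed = 12))
}

folded_gd <- function() {
  cached("folded_gd", function() geodesic_distance_matrix(folded_mesh()))
}

# Four-triangle strip whose edge-adjacency dual is a path graph
# T1 - T2 - T3 - T4 (T1/T3 and T2/T4 share only a vertex).
strip_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
             c(0.5, 1, 0), c(1.5, 1, 0), c(2.5, 1, 0))
  tr <- rbind(c(1L, 2L, 4L), c(2L, 5L, 4L), c(2L, 3L, 5L), c(3L, 6L, 5L))
  roi_mesh(v, tr)
}

# Candidate set with arbitrary placeholder configs around a toy map matrix.
toy_candidates <- function(maps) {
  candidate_set(as.matrix(maps))
}

# Random candidate instance generator used by the sampling equivalence
# checks: mixes continuous values, small-integer (tie-heavy) values and
# duplicated rows.
random_instance <- function(i) {
  nc <- sample(2:100, 1L)
  k <- sample(1:10, 1L)
  maps <- matrix(runif(nc * k), nc, k)
  if (i %% 3L == 0L) maps <- matrix(sample(0:3, nc * k, TRUE), nc, k) * 1.0
  if (i %% 4L == 0L && nc >= 4L) {
    maps[2L, ] <- maps[1L, ]
    maps[4L, ] <- maps[3L, ]
  }
  list(maps = maps,
       ns = sample(1:min(10L, nc), 1L),
       first = sample(nc, 1L))
}

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Small experiment configuration for orchestration tests.
tiny_config <- function(...) {
  args <- list(n_compartments = 150, patch_radius = 12, roi_radius = 10,
               search_radius = 10, spacing = 5, angle_step = 45,
               angle_max = 135, hr_spacing = 5, hr_angle_step = 45,
               budget = 50L, sampling_seeds = 1:2, noise_seeds = 1:2)
  over <- list(...)
  args[names(over)] <- over
  do.call(experiment_config, args)
}
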