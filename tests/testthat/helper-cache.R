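# Lazily computed shared fixtures (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small simulated dataset + features, shared by model-level tests
sim_small <- function() cached("sim_small", {
  bs <- simulate_blob_dataset(simulation_params(n_blobs_per_class = 100L, seed = 7L))
  features <- featurize_blobs(bs)
  list(bs = bs, features = features,
       labels = vapply(bs, function(b) b$class, character(1)))
})

blob_from_points <- function(pts, id = "b1", cell = "c1", class = NA_character_) {
  blob(id, pts, cell_id = cell, class = class)
}

# synthetic multi-cell experiment + one full pipeline run, shared by the
# pipeline and acceptance tests
fixture_data <- function() cached("fixture_data",
  simulate_experiment_fixture(seed = 42L))

fixture_run <- function() cached("fixture_run", suppressWarnings(
  run_real_pipeline(fixture_data()$eventlists, fixture_data()$masks,
                    n_test = 16L, n_val = 8L, n_trees = 50L, seed = 11L)))

# the full-scale simulated validation study (study defaults, seed 1)
sim_headline <- function() cached("sim_headline",
  validate_simulated(simulation_params(seed = 1L), k = 10L, n_trees = 100L,
                     cv_seed = 1L))
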