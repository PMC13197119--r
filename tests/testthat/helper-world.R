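# Shared synthetic fixtures, built once per test run. Sizes are scaled down
# from the generator defaults so the whole suite stays fast on one CPU.

.fixture_env <- new.env(parent = emptyenv())

shared_world <- function() {
  if (is.null(.fixture_env$world)) {
    .fixture_env$world <- generate_world(synthetic_config(
      n_regions = 500L, n_tfs = 3L, n_cells = 4L, seed = 42L))
  }
  .fixture_env$world
}

shared_features <- function() {
  if (is.null(.fixture_env$features)) {
    .fixture_env$features <- build_features(shared_world())
  }
  .fixture_env$features
}

# small booster settings for tests (defaults are the full-scale 500 rounds)
test_params <- function(nrounds = 60L) gbt_params(nrounds = nrounds)
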