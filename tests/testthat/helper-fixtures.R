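# Shared fixtures, built once per test run and cached in-process.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small, fast pipeline for unit tests: 300 genes, 1500 cells, short training
# schedule. Train on the first 1000 cells, keep 500 for prediction tests.
small_pipeline <- function() fixture("small", function() {
  params <- synthetic_params(n_genes = 300L, seed = 101L)
  ds <- simulate_dataset(params, 1500L)
  norm <- normalize_matrix(ds$counts, "pearson_residual")
  lognorm <- normalize_matrix(ds$counts, "log_cpm")
  tr <- 1:1000
  markers <- find_state_markers(lognorm[, tr], ds$labels[tr])
  space <- feature_space_from_markers(
    markers, state_names = intersect(CC_STATES, unique(ds$labels)))
  aligned <- align_features(norm, space)
  cfg <- model_config(rounds = 2L, epochs_per_round = 5L, seed = 11L)
  model <- train_classifier(build_classifier(cfg, space),
                            aligned$values[tr, ], ds$labels[tr])
  list(params = params, dataset = ds, norm = norm, lognorm = lognorm,
       markers = markers, space = space, aligned = aligned, model = model,
       train_idx = tr, test_idx = 1001:1500)
})

# Full study-condition pipeline: generator defaults (1000 genes, log2FC 2,
# dropout 0.2), 3000 training cells plus a held-out 1000-cell sample,
# Pearson-residual normalization, marker-derived feature space, default
# training schedule.
study_pipeline <- function() fixture("study", function() {
  params <- synthetic_params(seed = 202L)
  ds <- simulate_dataset(params, 4000L)
  tr <- 1:3000
  te <- 3001:4000
  norm <- normalize_matrix(ds$counts, "pearson_residual")
  lognorm <- normalize_matrix(ds$counts, "log_cpm")
  markers <- find_state_markers(lognorm[, tr], ds$labels[tr])
  space <- feature_space_from_markers(
    markers, state_names = intersect(CC_STATES, unique(ds$labels)))
  aligned <- align_features(norm, space)
  model <- train_classifier(build_classifier(model_config(seed = 7L), space),
                            aligned$values[tr, ], ds$labels[tr])
  list(params = params, dataset = ds, norm = norm, lognorm = lognorm,
       markers = markers, space = space, aligned = aligned, model = model,
       train_idx = tr, test_idx = te)
})

# The seven-state vocabulary, exported for readability in tests.
CC_STATES <- c("Neural G0", "G1", "Late G1", "S", "S/G2", "G2/M", "M/Early G1")
CC_CYCLING_STATES <- c("Late G1", "S", "S/G2", "G2/M", "M/Early G1")
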