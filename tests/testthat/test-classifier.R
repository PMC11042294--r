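dummy_space <- function(n_features, states = c("A", "B", "C", "D", "E", "F", "G")) {
  feature_space(sprintf("f%04d", seq_len(n_features)), state_names = states)
}

test_that("configuration enforces the funnel shape and parameter ranges", {
  expect_error(model_config(hidden1 = 100, hidden2 = 200), "funnel")
  expect_error(model_config(hidden2 = 5, n_classes = 7), "funnel")
  expect_error(model_config(dropout_rate = 1), "probability")
  expect_error(model_config(holdout_fraction = 0), "holdout_fraction")
  expect_error(build_classifier(model_config(), dummy_space(10, c("A"))),
               "funnel|2 states")
})

test_that("the default architecture has the expected closed-form parameter count", {
  # 861*600 + 600 + 600*200 + 200 + 200*7 + 7
  m <- build_classifier(model_config(seed = 1), dummy_space(861))
  expect_identical(glance(m)$n_params, 638807L)
  expect_identical(dim(m$weights$W1), c(861L, 600L))
  expect_identical(dim(m$weights$W3), c(200L, 7L))
})

test_that("initialization is seeded and forward passes are simplex rows", {
  sp <- dummy_space(30)
  m1 <- build_classifier(model_config(seed = 3), sp)
  m2 <- build_classifier(model_config(seed = 3), sp)
  m3 <- build_classifier(model_config(seed = 4), sp)
  expect_identical(m1$weights, m2$weights)
  expect_false(identical(m1$weights, m3$weights))

  zero <- matrix(0, nrow = 1, ncol = 30)
  lik <- suppressWarnings(predict_likelihoods(m1, zero))
  expect_equal(sum(lik$values), 1, tolerance = 1e-9)
  expect_true(all(lik$values >= 0))
})

test_that("training is deterministic, accurate on separable data, and at chance on shuffled labels", {
  fx <- small_pipeline()
  tr <- fx$train_idx
  x <- fx$aligned$values[tr, ]
  labs <- fx$dataset$labels[tr]
  hist1 <- fx$model$training_history
  cfg <- fx$model$config
  m2 <- train_classifier(build_classifier(cfg, fx$space), x, labs)
  expect_identical(hist1, m2$training_history)
  expect_identical(fx$model$weights, m2$weights)
  expect_gte(dplyr::last(hist1$holdout_accuracy), 0.9)

  shuffled <- withr::with_seed(5, sample(labs))
  cfg_small <- model_config(hidden1 = 48L, hidden2 = 16L, rounds = 1L,
                            epochs_per_round = 3L, seed = 9L)
  m_null <- train_classifier(build_classifier(cfg_small, fx$space), x, shuffled)
  chance <- max(table(labs)) / length(labs)
  expect_lt(abs(dplyr::last(m_null$training_history$holdout_accuracy) - chance),
            0.08)
})

test_that("training validates labels and class sizes", {
  fx <- small_pipeline()
  x <- fx$aligned$values[1:20, ]
  m <- build_classifier(fx$model$config, fx$space)
  expect_error(train_classifier(m, x, rep("Mitosis!", 20)), "Mitosis!")
  labs <- c("Neural G0", rep("G1", 19))
  expect_error(train_classifier(m, x, labs), "fewer than 2")
})

test_that("likelihood rows sum to one and duplicate cells get identical rows", {
  fx <- small_pipeline()
  x <- fx$aligned$values[fx$test_idx[1:20], ]
  x <- rbind(x, x[1, , drop = FALSE])
  lik <- predict_likelihoods(fx$model, x)
  expect_true(all(abs(rowSums(lik$values) - 1) < 1e-6))
  expect_equal(unname(lik$values[21, ]), unname(lik$values[1, ]))
  expect_error(predict_likelihoods(fx$model, x[, 1:5]), "expects")
})

test_that("permuting cell order permutes outputs identically", {
  fx <- small_pipeline()
  x <- fx$aligned$values[fx$test_idx[1:50], ]
  perm <- withr::with_seed(2, sample(50))
  lik <- predict_likelihoods(fx$model, x)
  lik_p <- predict_likelihoods(fx$model, x[perm, ])
  expect_equal(unname(lik_p$values), unname(lik$values[perm, ]))
})

test_that("the modal predicted state matches the true state on planted data", {
  fx <- small_pipeline()
  lik <- predict_likelihoods(fx$model, fx$aligned$values[fx$test_idx, ])
  pred <- assign_states(lik, threshold = 0)
  truth <- fx$dataset$labels[fx$test_idx]
  for (s in unique(truth)) {
    modal <- names(which.max(table(pred$label[truth == s])))
    expect_identical(modal, s)
  }
})

test_that("threshold rejection follows the decision rule exactly", {
  lik <- structure(list(
    values = rbind(c(0.6, 0.1, 0.1, 0.1, 0.05, 0.03, 0.02),
                   c(0.49, 0.10, 0.10, 0.10, 0.09, 0.06, 0.06),
                   c(0.50, 0.10, 0.10, 0.10, 0.08, 0.06, 0.06)),
    state_names = CC_STATES, cell_ids = c("a", "b", "c")),
    class = "cc_likelihood")
  a <- assign_states(lik, threshold = 0.5)
  expect_identical(a$label, c("Neural G0", "Unknown", "Neural G0"))
  expect_identical(a$threshold, rep(0.5, 3))
  expect_true(all((a$label == "Unknown") == (a$max_likelihood < 0.5)))

  a0 <- assign_states(lik, threshold = 0)
  expect_false(any(a0$label == "Unknown"))
  expect_error(assign_states(lik, threshold = 1.2), "0, 1")
})

test_that("rejection is monotone across the threshold grid", {
  withr::with_seed(11, {
    raw <- matrix(rexp(200 * 7), ncol = 7)
    lik <- structure(list(values = raw / rowSums(raw),
                          state_names = CC_STATES,
                          cell_ids = sprintf("c%03d", 1:200)),
                     class = "cc_likelihood")
  })
  kept <- lapply(seq(0, 0.9, 0.1), function(t) {
    a <- assign_states(lik, t)
    a$cell_id[a$label != "Unknown"]
  })
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("G0/G1 collapse merges exactly the three G0/G1-adjacent labels", {
  expect_identical(collapse_g0g1(c("Neural G0", "Late G1", "S")),
                   c("G0/G1", "G0/G1", "S"))
  expect_identical(collapse_g0g1("Unknown"), "Unknown")
  labs <- c(CC_STATES, "Unknown")
  once <- collapse_g0g1(labs)
  expect_identical(collapse_g0g1(once), once)
  expect_setequal(unique(once), c("G0/G1", "S", "S/G2", "G2/M", "M/Early G1",
                                  "Unknown"))
})

test_that("model archives round-trip bit-for-bit and reject bad files", {
  fx <- small_pipeline()
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(fx$model, path)
  back <- load_classifier(path)
  expect_identical(back$weights, fx$model$weights)
  expect_identical(back$feature_space$feature_ids, fx$space$feature_ids)
  expect_identical(back$feature_space$state_names, fx$space$state_names)
  x <- fx$aligned$values[fx$test_idx[1:30], ]
  expect_identical(predict_likelihoods(back, x)$values,
                   predict_likelihoods(fx$model, x)$values)

  truncated <- withr::local_tempfile(fileext = ".json")
  full <- readChar(path, file.size(path))
  writeChar(substr(full, 1, nchar(full) %/% 2), truncated)
  expect_error(load_classifier(truncated), "archive")
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else"), other)
  expect_error(load_classifier(other), "not a ccann model")
})

test_that("tidy and glance summarize a fitted classifier", {
  fx <- small_pipeline()
  td <- tidy(fx$model)
  expect_identical(nrow(td),
                   fx$model$config$rounds * fx$model$config$epochs_per_round)
  expect_named(td, c("round", "epoch", "holdout_loss", "holdout_accuracy"))
  gl <- glance(fx$model)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$trained)
  expect_identical(gl$n_states, 7L)
})
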