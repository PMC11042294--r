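test_that("per-state F1 matches hand computations and closed forms", {
  truth <- c("A", "A", "B", "B", "C", "C")
  pred <- c("A", "B", "B", "B", "C", "A")
  f1 <- f1_per_state(truth, pred)
  by_state <- setNames(f1$f1, f1$state)
  # A: tp=1 fp=1 fn=1; B: tp=2 fp=1 fn=0; C: tp=1 fp=0 fn=1
  expect_equal(unname(by_state["A"]), 2 * 1 / (2 + 1 + 1))
  expect_equal(unname(by_state["B"]), 2 * 2 / (4 + 1 + 0))
  expect_equal(unname(by_state["C"]), 2 * 1 / (2 + 0 + 1))

  perfect <- f1_per_state(truth, truth)
  expect_true(all(perfect$f1 == 1))

  # constant prediction: F1(s) = 2 prev / (1 + prev)
  const <- f1_per_state(truth, rep("A", 6))
  prev <- 1 / 3
  expect_equal(const$f1[const$state == "A"], 2 * prev / (1 + prev))
  expect_identical(const$f1[const$state == "B"], 0)
  expect_error(f1_per_state(truth, pred[1:3]), "length")
  expect_error(f1_per_state(c("A", "Unknown"), c("A", "A")), "rejection")
})

test_that("Unknown predictions count against recall but never precision", {
  truth <- c("A", "A", "B")
  pred <- c("A", "Unknown", "A")
  f1 <- f1_per_state(truth, pred)
  expect_equal(f1$precision[f1$state == "A"], 0.5)
  expect_equal(f1$recall[f1$state == "A"], 0.5)
  expect_equal(classification_error(truth, pred), 1 / 2)
  expect_equal(classification_error(truth, pred, include_unknown = TRUE), 2 / 3)
  expect_warning(e <- classification_error(truth, rep("Unknown", 3)),
                 "undefined")
  expect_true(is.na(e))
  expect_equal(classification_error(truth, truth), 0)
})

test_that("AMI matches the brute-force oracle exhaustively on small labelings", {
  # every pair of 2-valued labelings of 5 items
  grids <- expand.grid(rep(list(1:2), 5))
  for (i in seq_len(nrow(grids))) {
    for (j in seq_len(nrow(grids))) {
      u <- paste0("s", as.integer(grids[i, ]))
      v <- paste0("t", as.integer(grids[j, ]))
      expect_equal(ami_score(u, v, exclude_unknown = FALSE),
                   ami_oracle(u, v), tolerance = 1e-10)
    }
  }
})

test_that("AMI matches the oracle on random 8-item labelings with up to 4 clusters", {
  withr::with_seed(19, {
    for (rep in 1:40) {
      u <- sample(letters[1:4], 8, replace = TRUE)
      v <- sample(LETTERS[1:3], 8, replace = TRUE)
      expect_equal(ami_score(u, v, exclude_unknown = FALSE),
                   ami_oracle(u, v), tolerance = 1e-10)
    }
  })
})

test_that("AMI is 1 for relabelings, symmetric, and excludes Unknowns", {
  truth <- rep(c("A", "B", "C"), times = c(5, 3, 4))
  bijection <- c(A = "x", B = "y", C = "z")[truth]
  expect_equal(ami_score(truth, truth), 1)
  expect_equal(ami_score(truth, unname(bijection)), 1)

  withr::with_seed(23, {
    u <- sample(c("A", "B"), 30, replace = TRUE)
    v <- sample(c("x", "y", "z"), 30, replace = TRUE)
  })
  expect_equal(ami_score(u, v, exclude_unknown = FALSE),
               ami_score(v, u, exclude_unknown = FALSE), tolerance = 1e-12)

  # Unknown cells are dropped before computing the score
  pred <- truth
  pred[1:3] <- "Unknown"
  expect_equal(ami_score(truth, pred),
               ami_score(truth[-(1:3)], pred[-(1:3)], exclude_unknown = FALSE))
  expect_error(ami_score(c("A", "B"), c("Unknown", "Unknown")), "at least 2")
})

test_that("cross-validation produces k stratified folds with strong F1 on planted data", {
  fx <- small_pipeline()
  idx <- fx$train_idx[1:600]
  cfg <- model_config(hidden1 = 64L, hidden2 = 24L, rounds = 1L,
                      epochs_per_round = 6L, seed = 2L)
  cv <- cross_validate(fx$aligned$values[idx, ], fx$dataset$labels[idx],
                       k = 3, config = cfg, threshold = 0, seed = 77)
  expect_identical(nrow(cv), 3L * 7L)
  expect_true(all(table(cv$state) == 3))
  med <- median(tapply(cv$f1, cv$fold, mean, na.rm = TRUE))
  expect_gte(med, 0.85)
  cv2 <- cross_validate(fx$aligned$values[idx, ], fx$dataset$labels[idx],
                        k = 3, config = cfg, threshold = 0, seed = 77)
  expect_identical(cv, cv2)
  expect_error(cross_validate(fx$aligned$values[idx, ],
                              fx$dataset$labels[idx], k = 500), "fewer than")
})

test_that("the AMI calibration curve hits its anchors on a small grid", {
  cal <- simulate_ami_calibration(k_ref = 3:4, k_pred = 3:4,
                                  similarities = c(0, 0.5, 1),
                                  n_cells = 400, n_reps = 25, seed = 6)
  expect_identical(nrow(cal), 2L * 2L * 3L)
  top <- cal[cal$similarity == 1 & cal$k_ref == cal$k_pred, ]
  expect_true(all(abs(top$mean_ami - 1) < 1e-9))
  bottom <- cal[cal$similarity == 0, ]
  expect_true(all(abs(bottom$mean_ami) < 0.03))
  # monotone in similarity for each (k_ref, k_pred)
  for (kr in 3:4) for (kp in 3:4) {
    sub <- cal[cal$k_ref == kr & cal$k_pred == kp, ]
    sub <- sub[order(sub$similarity), ]
    expect_true(all(diff(sub$mean_ami) > -0.05))
  }
  expect_error(simulate_ami_calibration(k_ref = 1), "at least 2")
  expect_error(simulate_ami_calibration(similarities = c(-0.1)), "0, 1")
})

test_that("threshold sweeps are monotone with a faithful baseline at zero", {
  fx <- small_pipeline()
  te <- fx$test_idx
  lik <- predict_likelihoods(fx$model, fx$aligned$values[te, ])
  sw <- threshold_sweep(lik, fx$dataset$labels[te], subsample = 0.9,
                        seed = 3)
  expect_identical(nrow(sw), 10L)
  expect_true(all(diff(sw$pct_predicted) <= 0))
  expect_equal(sw$pct_predicted[1], 100)
  # at threshold 0 nothing is removed, so baseline and sweep AMI coincide
  expect_equal(sw$ami[1], sw$baseline_ami[1])
  sw2 <- threshold_sweep(lik, fx$dataset$labels[te], subsample = 0.9,
                         seed = 3)
  expect_identical(sw, sw2)
  expect_error(threshold_sweep(lik, fx$dataset$labels[1:5]), "cover")
})

test_that("missing-gene sensitivity approaches the unperturbed error as the fraction vanishes", {
  fx <- small_pipeline()
  te <- fx$test_idx
  x <- fx$aligned$values[te, ]
  truth <- fx$dataset$labels[te]
  base_pred <- assign_states(predict_likelihoods(fx$model, x), 0.5)
  base_err <- classification_error(truth, base_pred$label)

  tiny <- missing_gene_sensitivity(fx$model, x, truth,
                                   fractions = 1 / ncol(x), n_reps = 3,
                                   thresholds = 0.5, seed = 8)
  expect_lt(max(abs(tiny$error_rate - base_err)), 0.05)
  expect_true(all(tiny$pct_predicted >= 0 & tiny$pct_predicted <= 100))
  expect_error(missing_gene_sensitivity(fx$model, x, truth, fractions = 0),
               "between 0 and 1")
  expect_error(missing_gene_sensitivity(fx$model, x, truth, fractions = 1),
               "between 0 and 1")
})

test_that("raising the threshold at a fixed missing fraction never keeps extra cells", {
  fx <- small_pipeline()
  te <- fx$test_idx[1:200]
  sens <- missing_gene_sensitivity(fx$model, fx$aligned$values[te, ],
                                   fx$dataset$labels[te],
                                   fractions = 0.3, n_reps = 3,
                                   thresholds = c(0.5, 0.9), seed = 12)
  wide <- tidyr::pivot_wider(sens, id_cols = "replicate",
                             names_from = "threshold",
                             values_from = "pct_predicted")
  expect_true(all(wide[["0.9"]] <= wide[["0.5"]]))
})

test_that("the hidden-layer grid search ranks reproducibly and keeps the funnel", {
  fx <- small_pipeline()
  idx <- fx$train_idx[1:500]
  cfg <- model_config(rounds = 1L, epochs_per_round = 4L, seed = 3L)
  gs <- grid_search_hidden(fx$aligned$values[idx, ], fx$dataset$labels[idx],
                           hidden1 = c(32L, 64L), hidden2 = c(16L, 48L),
                           config = cfg, seed = 10)
  # funnel filter: (32,16), (64,16), (64,48)
  expect_identical(nrow(gs), 3L)
  expect_true(all(gs$hidden1 > gs$hidden2))
  expect_identical(gs$rank, 1:3)
  gs2 <- grid_search_hidden(fx$aligned$values[idx, ], fx$dataset$labels[idx],
                            hidden1 = c(32L, 64L), hidden2 = c(16L, 48L),
                            config = cfg, seed = 10)
  expect_identical(gs, gs2)

  one <- grid_search_hidden(fx$aligned$values[idx, ], fx$dataset$labels[idx],
                            hidden1 = 48L, hidden2 = 24L, config = cfg,
                            seed = 10)
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$hidden1, one$hidden2), c(48L, 24L))
  # the default grid contains the canonical 600/200 configuration
  full <- expand.grid(hidden1 = seq(200L, 700L, 100L),
                      hidden2 = seq(100L, 400L, 100L))
  full <- full[full$hidden1 > full$hidden2, ]
  expect_identical(nrow(full), 18L)
  expect_true(any(full$hidden1 == 600L & full$hidden2 == 200L))
})
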