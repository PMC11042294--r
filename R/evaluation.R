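#' Per-state F1 scores
#'
#' One-vs-rest precision, recall and F1 for every state present in either
#' labeling. `"Unknown"` is allowed in `pred` only: a rejected cell counts
#' as a missed prediction (false negative) for its true state but is never a
#' false positive. States absent from both labelings are simply not
#' reported; F1 is `NA` when a state has no true or predicted cells.
#'
#' @param truth,pred Same-length label vectors.
#' @return A tibble with columns `state`, `precision`, `recall`, `f1`,
#'   `support`; the macro-averaged F1 is in `attr(, "macro_f1")`.
#' @export
f1_per_state <- function(truth, pred) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    stop_ccann("`truth` and `pred` must have the same length",
               class = "ccann_shape_error")
  }
  if (any(truth == "Unknown")) {
    stop_ccann("'Unknown' is a rejection label and may appear in `pred` only")
  }
  states <- unique(c(truth, setdiff(pred, "Unknown")))
  if (all(states %in% CC_STATES)) {
    states <- intersect(CC_STATES, states)
  }
  rows <- lapply(states, function(s) {
    tp <- sum(truth == s & pred == s)
    fp <- sum(pred == s & truth != s)
    fn <- sum(truth == s & pred != s)
    tibble(
      state = s,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
      support = sum(truth == s)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "macro_f1") <- mean(out$f1, na.rm = TRUE)
  out
}

#' Macro-averaged F1
#'
#' @param truth,pred Same-length label vectors.
#' @return Mean of the defined per-state F1 scores.
#' @export
macro_f1 <- function(truth, pred) attr(f1_per_state(truth, pred), "macro_f1")

#' Classification error rate
#'
#' Fraction of misclassified cells. By default cells predicted `"Unknown"`
#' are excluded from both numerator and denominator (the rejection option is
#' abstention, not error); set `include_unknown = TRUE` to count rejections
#' as errors over all cells instead.
#'
#' @param truth,pred Same-length label vectors.
#' @param include_unknown Count `"Unknown"` predictions as errors.
#' @return Error rate in `[0, 1]`; `NA` (with a warning) when no cell was
#'   classified.
#' @export
classification_error <- function(truth, pred, include_unknown = FALSE) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    stop_ccann("`truth` and `pred` must have the same length",
               class = "ccann_shape_error")
  }
  if (include_unknown) return(mean(truth != pred))
  classified <- pred != "Unknown"
  if (!any(classified)) {
    rlang::warn("no classified cells; error rate is undefined")
    return(NA_real_)
  }
  mean(truth[classified] != pred[classified])
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance under the permutation model,
#' normalized by the arithmetic mean of the two label entropies:
#' `AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI])`. AMI is symmetric,
#' invariant to relabeling, 1 for identical partitions and about 0 for
#' independent ones. Cells predicted `"Unknown"` are dropped before the
#' computation when `exclude_unknown` is set (rejected cells carry no
#' assignment to agree or disagree on).
#'
#' @param truth,pred Same-length label vectors.
#' @param exclude_unknown Drop cells with `pred == "Unknown"` first.
#' @return The AMI score (a scalar, at most 1).
#' @export
ami_score <- function(truth, pred, exclude_unknown = TRUE) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    stop_ccann("`truth` and `pred` must have the same length",
               class = "ccann_shape_error")
  }
  if (exclude_unknown) {
    keep <- pred != "Unknown"
    truth <- truth[keep]
    pred <- pred[keep]
  }
  if (length(truth) < 2) {
    stop_ccann("need at least 2 cells after Unknown exclusion")
  }
  ti <- match(truth, unique(truth))
  pi <- match(pred, unique(pred))
  ami_int(ti, pi, max(ti), max(pi))
}

# AMI on integer labels 1..kr / 1..kp. Fast path shared with the
# calibration simulation.
ami_int <- function(ti, pi, kr, kp) {
  n <- length(ti)
  cont <- matrix(tabulate(ti + kr * (pi - 1L), nbins = kr * kp),
                 nrow = kr, ncol = kp)
  a <- rowSums(cont)
  b <- colSums(cont)
  kr_eff <- sum(a > 0)
  kp_eff <- sum(b > 0)
  if (kr_eff == 1 && kp_eff == 1) return(1)   # single cluster on both sides

  nz <- which(cont > 0, arr.ind = TRUE)
  nij <- cont[nz]
  mi <- sum(nij / n * (log(nij) + log(n) - log(a[nz[, 1]]) - log(b[nz[, 2]])))
  h_u <- -sum(a[a > 0] / n * log(a[a > 0] / n))
  h_v <- -sum(b[b > 0] / n * log(b[b > 0] / n))

  emi <- expected_mi(a[a > 0], b[b > 0], n)
  normalizer <- (h_u + h_v) / 2
  denom <- normalizer - emi
  eps <- .Machine$double.eps
  denom <- if (denom < 0) min(denom, -eps) else max(denom, eps)
  (mi - emi) / denom
}

# Expected mutual information under the permutation (hypergeometric) model.
expected_mi <- function(a, b, n) {
  lg <- lgamma(seq_len(n + 1))               # lgamma(k + 1) = lg[k + 1]
  lfac <- function(k) lg[k + 1]
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      log_p <- lfac(ai) + lfac(bj) + lfac(n - ai) + lfac(n - bj) -
        lfac(n) - lfac(nij) - lfac(ai - nij) - lfac(bj - nij) -
        lfac(n - ai - bj + nij)
      emi <- emi + sum(nij / n * (log(n) + log(nij) - log(ai) - log(bj)) *
                         exp(log_p))
    }
  }
  emi
}

# Feature space inferred from an aligned matrix plus a label vocabulary.
space_for_data <- function(data, labels, state_names = NULL) {
  x <- if (inherits(data, "cc_aligned")) data$values else data
  if (is.null(state_names)) {
    u <- unique(as.character(labels))
    state_names <- if (all(u %in% CC_STATES)) intersect(CC_STATES, u) else u
  }
  feature_space(colnames(x) %||% sprintf("f%05d", seq_len(ncol(x))),
                state_names = state_names)
}

#' Repeated-split cross-validation of the classifier
#'
#' `k` independent repetitions of a class-stratified random
#' `1 - holdout` / `holdout` split: a fresh model is trained on the large
#' part and per-state F1 is scored on the held-out part. Deterministic under
#' `seed`.
#'
#' @param data A `cc_aligned` or cells x features matrix.
#' @param labels Per-cell state names; every class needs at least `k` cells.
#' @param k Number of repetitions (default 10).
#' @param holdout Held-out fraction per repetition (default 0.2).
#' @param config A [model_config()] template (its seed is re-derived per
#'   fold).
#' @param threshold Likelihood threshold applied when scoring.
#' @param seed Seed for the splits.
#' @return A tibble with columns `fold`, `state`, `precision`, `recall`,
#'   `f1`, `support` (k rows per state).
#' @export
cross_validate <- function(data, labels, k = 10L, holdout = 0.2,
                           config = model_config(), threshold = 0.5,
                           seed = 1L) {
  k <- check_count(k, "k")
  x <- if (inherits(data, "cc_aligned")) data$values else data
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop_ccann(sprintf("class(es) with fewer than k = %d cells: %s", k,
                       paste(names(tab)[tab < k], collapse = ", ")))
  }
  space <- space_for_data(data, labels)
  splits <- withr::with_seed(derive_seed(seed, "cv_splits"), {
    lapply(seq_len(k), function(i) {
      unlist(lapply(unique(labels), function(s) {
        idx <- which(labels == s)
        sample(idx, size = max(1L, round(holdout * length(idx))))
      }))
    })
  })
  res <- lapply(seq_len(k), function(i) {
    test_idx <- splits[[i]]
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("cv_fold", i))
    cfg$n_features <- NULL
    model <- build_classifier(cfg, space)
    model <- train_classifier(model, x[train_idx, , drop = FALSE],
                              labels[train_idx])
    lik <- predict_likelihoods(model, x[test_idx, , drop = FALSE])
    pred <- assign_states(lik, threshold = threshold)
    dplyr::mutate(f1_per_state(labels[test_idx], pred$label), fold = i,
                  .before = 1)
  })
  dplyr::bind_rows(res)
}

#' Simulate the AMI similarity calibration curve
#'
#' AMI depends on how many states the reference and the classifier each
#' use, so a raw AMI is hard to read across classifiers. This simulation
#' calibrates it: reference labels are drawn uniformly over `k_ref` states;
#' for each similarity `s`, a fraction `s` of cells (rounded) copy their
#' reference label (mapped through the fixed surjection
#' `state i -> ((i - 1) mod k_pred) + 1` when the vocabularies differ) and
#' the rest draw uniformly from the `k_pred` vocabulary. The mean AMI over
#' `n_reps` replicates is recorded per (k_ref, k_pred, s).
#'
#' @param k_ref,k_pred Reference / predicted state counts (vectors allowed;
#'   every combination is simulated).
#' @param similarities Similarity grid in `[0, 1]` (default 0 to 1 by 0.1).
#' @param n_cells Cells per replicate (default 1000).
#' @param n_reps Replicates per grid point (default 100).
#' @param seed Seed for the whole simulation.
#' @return A tibble of class `cc_calibration` with columns `k_ref`,
#'   `k_pred`, `similarity`, `mean_ami`, `n_reps`.
#' @export
simulate_ami_calibration <- function(k_ref = 3:8, k_pred = 3:8,
                                     similarities = seq(0, 1, by = 0.1),
                                     n_cells = 1000L, n_reps = 100L,
                                     seed = 1L) {
  if (any(k_ref < 2) || any(k_pred < 2)) {
    stop_ccann("state counts must be at least 2", class = "ccann_invalid_parameter")
  }
  if (any(similarities < 0 | similarities > 1)) {
    stop_ccann("similarities must lie in [0, 1]", class = "ccann_invalid_parameter")
  }
  n_cells <- check_count(n_cells, "n_cells", min = 2L)
  n_reps <- check_count(n_reps, "n_reps")
  grid <- expand.grid(k_ref = k_ref, k_pred = k_pred,
                      similarity = similarities, KEEP.OUT.ATTRS = FALSE)
  out <- withr::with_seed(seed, {
    mean_ami <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      kr <- grid$k_ref[g]
      kp <- grid$k_pred[g]
      s <- grid$similarity[g]
      n_copy <- round(s * n_cells)
      amis <- vapply(seq_len(n_reps), function(r) {
        ref <- sample.int(kr, n_cells, replace = TRUE)
        pred <- sample.int(kp, n_cells, replace = TRUE)
        if (n_copy > 0) {
          copied <- sample.int(n_cells, n_copy)
          pred[copied] <- (ref[copied] - 1L) %% kp + 1L
        }
        ami_int(ref, pred, kr, kp)
      }, numeric(1))
      mean_ami[g] <- mean(amis)
    }
    mean_ami
  })
  res <- as_tibble(grid)
  res$mean_ami <- out
  res$n_reps <- n_reps
  class(res) <- c("cc_calibration", class(res))
  res
}

#' Likelihood-threshold sweep with a random-removal baseline
#'
#' Sweeps the rejection threshold over a grid (default 0.0 to 0.9 by 0.1) on
#' a random subsample of cells: for each threshold the percentage of cells
#' still classified and the AMI of the surviving classifications against the
#' reference are recorded. The baseline removes the *same number* of cells
#' uniformly at random instead of by likelihood; if thresholding helps
#' because it rejects genuinely uncertain cells, the thresholded AMI rises
#' while the baseline stays flat. AMI is left undefined (NA) when
#' `min_cells` or fewer cells survive.
#'
#' @param lik A `cc_likelihood`.
#' @param reference Per-cell reference labels (same order as the
#'   likelihoods).
#' @param thresholds Threshold grid.
#' @param subsample Fraction of cells subsampled before the sweep
#'   (default 0.9).
#' @param min_cells Minimum surviving cells for metrics (default 20).
#' @param seed Seed for subsampling and the baseline removal.
#' @return A tibble of class `cc_sweep` with columns `threshold`,
#'   `n_predicted`, `pct_predicted`, `ami`, `baseline_ami`.
#' @export
threshold_sweep <- function(lik, reference,
                            thresholds = seq(0, 0.9, by = 0.1),
                            subsample = 0.9, min_cells = 20L, seed = 1L) {
  stopifnot(inherits(lik, "cc_likelihood"))
  reference <- as.character(reference)
  if (length(reference) != nrow(lik$values)) {
    stop_ccann("`reference` must cover all cells", class = "ccann_shape_error")
  }
  check_prob(subsample, "subsample")
  withr::with_seed(seed, {
    n <- nrow(lik$values)
    sub <- sort(sample.int(n, size = max(2L, round(subsample * n))))
    p <- lik$values[sub, , drop = FALSE]
    ref <- reference[sub]
    win <- lik$state_names[max.col(p, ties.method = "first")]
    max_lik <- p[cbind(seq_len(nrow(p)), max.col(p, ties.method = "first"))]
    n_sub <- length(sub)
    rows <- lapply(thresholds, function(t) {
      keep <- max_lik >= t
      n_pred <- sum(keep)
      ami <- if (n_pred > min_cells) ami_score(ref[keep], win[keep]) else NA_real_
      base_keep <- sample.int(n_sub, n_pred)
      baseline <- if (n_pred > min_cells) {
        ami_score(ref[base_keep], win[base_keep])
      } else NA_real_
      tibble(threshold = t, n_predicted = n_pred,
             pct_predicted = 100 * n_pred / n_sub,
             ami = ami, baseline_ami = baseline)
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("cc_sweep", class(out))
    out
  })
}

#' Sensitivity of the classifier to missing genes
#'
#' Emulates dropout of classifier input genes: for each missing fraction and
#' replicate, a seeded random subset of feature columns is set to zero for
#' *all* cells (at the classifier-input scale), states are assigned at each
#' threshold, and the error rate (Unknown-excluded by default) and
#' percentage of cells still classified are recorded.
#'
#' @param model A trained `cc_classifier`.
#' @param data A `cc_aligned` or cells x features matrix.
#' @param truth Per-cell true state names.
#' @param fractions Missing fractions, each in (0, 1).
#' @param n_reps Replicates per fraction (default 10).
#' @param thresholds Likelihood thresholds to evaluate (default 0.5).
#' @param include_unknown Passed to [classification_error()].
#' @param seed Seed for the gene subsets.
#' @return A tibble of class `cc_sensitivity` with columns
#'   `fraction_missing`, `replicate`, `threshold`, `error_rate`,
#'   `pct_predicted`.
#' @export
missing_gene_sensitivity <- function(model, data, truth,
                                     fractions = c(0.1, 0.2, 0.4, 0.7),
                                     n_reps = 10L, thresholds = 0.5,
                                     include_unknown = FALSE, seed = 1L) {
  stopifnot(inherits(model, "cc_classifier"))
  if (any(fractions <= 0 | fractions >= 1)) {
    stop_ccann("fractions must lie strictly between 0 and 1",
               class = "ccann_invalid_parameter")
  }
  n_reps <- check_count(n_reps, "n_reps")
  x <- aligned_values(data, model$feature_space)
  truth <- as.character(truth)
  if (length(truth) != nrow(x)) {
    stop_ccann("`truth` length must match the number of cells",
               class = "ccann_shape_error")
  }
  n_feat <- ncol(x)
  rows <- list()
  for (f in fractions) {
    for (rep in seq_len(n_reps)) {
      cols <- withr::with_seed(
        derive_seed(seed, sprintf("missing_%g_%d", f, rep)),
        sample.int(n_feat, size = max(1L, round(f * n_feat)))
      )
      x2 <- x
      x2[, cols] <- 0
      lik <- predict_likelihoods(model, x2)
      for (t in thresholds) {
        pred <- assign_states(lik, threshold = t)
        err <- suppressWarnings(
          classification_error(truth, pred$label,
                               include_unknown = include_unknown))
        rows[[length(rows) + 1]] <- tibble(
          fraction_missing = f, replicate = rep, threshold = t,
          error_rate = err,
          pct_predicted = 100 * mean(pred$label != "Unknown")
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cc_sensitivity", class(out))
  out
}

#' Grid search over hidden-layer widths
#'
#' Trains one model per (hidden1, hidden2) combination on a shared
#' stratified split and ranks configurations by mean F1 on the held-out
#' cells, then by mean AMI over any supplied evaluation sets. Combinations
#' are restricted to the funnel shape `hidden1 > hidden2` by default.
#'
#' @param data A `cc_aligned` or cells x features matrix.
#' @param labels Per-cell state names.
#' @param hidden1,hidden2 Candidate widths (defaults 200--700 and 100--400
#'   by 100).
#' @param funnel_only Keep only combinations with `hidden1 > hidden2`.
#' @param eval_sets Optional list of `list(data = , reference = )` pairs for
#'   the AMI column.
#' @param config A [model_config()] template.
#' @param holdout Held-out fraction for the F1 score.
#' @param threshold Likelihood threshold applied when scoring.
#' @param seed Seed for the shared split and per-config training.
#' @return A tibble with columns `hidden1`, `hidden2`, `mean_f1`,
#'   `mean_ami`, `rank`, ordered best first.
#' @export
grid_search_hidden <- function(data, labels,
                               hidden1 = seq(200L, 700L, by = 100L),
                               hidden2 = seq(100L, 400L, by = 100L),
                               funnel_only = TRUE, eval_sets = NULL,
                               config = model_config(), holdout = 0.2,
                               threshold = 0.5, seed = 1L) {
  grid <- expand.grid(hidden1 = hidden1, hidden2 = hidden2,
                      KEEP.OUT.ATTRS = FALSE)
  if (funnel_only) grid <- grid[grid$hidden1 > grid$hidden2, , drop = FALSE]
  if (nrow(grid) == 0) stop_ccann("empty configuration grid")
  x <- if (inherits(data, "cc_aligned")) data$values else data
  labels <- as.character(labels)
  space <- space_for_data(data, labels)
  test_idx <- withr::with_seed(derive_seed(seed, "grid_split"), {
    unlist(lapply(unique(labels), function(s) {
      idx <- which(labels == s)
      sample(idx, size = max(1L, round(holdout * length(idx))))
    }))
  })
  train_idx <- setdiff(seq_len(nrow(x)), test_idx)

  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$hidden1 <- grid$hidden1[g]
    cfg$hidden2 <- grid$hidden2[g]
    cfg$n_features <- NULL
    cfg$seed <- derive_seed(seed, sprintf("grid_%d_%d", cfg$hidden1, cfg$hidden2))
    model <- build_classifier(cfg, space)
    model <- train_classifier(model, x[train_idx, , drop = FALSE],
                              labels[train_idx])
    pred <- assign_states(
      predict_likelihoods(model, x[test_idx, , drop = FALSE]),
      threshold = threshold)
    mean_f1 <- attr(f1_per_state(labels[test_idx], pred$label), "macro_f1")
    mean_ami <- if (is.null(eval_sets)) NA_real_ else {
      mean(vapply(eval_sets, function(es) {
        p <- assign_states(predict_likelihoods(model, es$data),
                           threshold = threshold)
        ami_score(es$reference, p$label)
      }, numeric(1)))
    }
    tibble(hidden1 = grid$hidden1[g], hidden2 = grid$hidden2[g],
           mean_f1 = mean_f1, mean_ami = mean_ami)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$mean_f1),
                   dplyr::desc(ifelse(is.na(.data$mean_ami), -Inf,
                                      .data$mean_ami)))
  out$rank <- seq_len(nrow(out))
  out
}
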