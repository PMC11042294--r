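#' Classifier model configuration
#'
#' Architecture and training hyperparameters for the cell-cycle ANN. The
#' network is a funnel: `n_features` inputs, two ReLU hidden layers
#' (default 600 and 200 neurons), a softmax output with one neuron per state,
#' and two dropout layers (rate 0.5) between the hidden layers and before the
#' output. Training minimizes categorical cross-entropy by minibatch SGD
#' with momentum and runs `rounds` consecutive repeats of `epochs_per_round`
#' epochs; each round redraws a random `holdout_fraction` split whose held-out
#' part is only used to monitor accuracy.
#'
#' @param n_features Number of input genes (set from the feature space at
#'   build time when `NULL`).
#' @param hidden1,hidden2 Hidden layer widths; must satisfy
#'   `hidden1 > hidden2 > n_classes`.
#' @param n_classes Number of output states.
#' @param dropout_rate Training-time dropout probability in `[0, 1)`.
#' @param epochs_per_round,rounds Training schedule (default 10 epochs x 5
#'   rounds).
#' @param holdout_fraction Fraction held out each round to monitor accuracy.
#' @param learning_rate,momentum,batch_size SGD hyperparameters.
#' @param seed Seed driving initialization, splits, shuffling and dropout.
#' @return An object of class `cc_model_config`.
#' @export
model_config <- function(n_features = NULL, hidden1 = 600L, hidden2 = 200L,
                         n_classes = 7L, dropout_rate = 0.5,
                         epochs_per_round = 10L, rounds = 5L,
                         holdout_fraction = 0.2, learning_rate = 0.01,
                         momentum = 0.9, batch_size = 32L, seed = 1L) {
  hidden1 <- check_count(hidden1, "hidden1")
  hidden2 <- check_count(hidden2, "hidden2")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  if (!(hidden1 > hidden2 && hidden2 > n_classes)) {
    stop_ccann("layer sizes must funnel: hidden1 > hidden2 > n_classes",
               class = "ccann_invalid_parameter")
  }
  check_prob(dropout_rate, "dropout_rate", closed_top = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop_ccann("`holdout_fraction` must be in (0, 1)",
               class = "ccann_invalid_parameter")
  }
  structure(
    list(n_features = if (is.null(n_features)) NULL else
           check_count(n_features, "n_features"),
         hidden1 = hidden1, hidden2 = hidden2, n_classes = n_classes,
         dropout_rate = dropout_rate,
         epochs_per_round = check_count(epochs_per_round, "epochs_per_round"),
         rounds = check_count(rounds, "rounds"),
         holdout_fraction = holdout_fraction,
         learning_rate = learning_rate, momentum = momentum,
         batch_size = check_count(batch_size, "batch_size"),
         seed = as.integer(seed)),
    class = "cc_model_config"
  )
}

#' Build an untrained cell-cycle classifier
#'
#' Instantiates the dense network for a feature space: weights are drawn
#' He-style (uniform, fan-in scaled) from a stream seeded by `config$seed`,
#' biases start at zero. The output layer width always equals the number of
#' states in the feature space.
#'
#' @param config A [model_config()].
#' @param space A [feature_space()] providing input genes and the state
#'   vocabulary.
#' @return An object of class `cc_classifier` with elements `config`,
#'   `feature_space`, `weights`, `trained`, `training_history`.
#' @export
build_classifier <- function(config = model_config(), space) {
  stopifnot(inherits(config, "cc_model_config"),
            inherits(space, "cc_feature_space"))
  n_features <- config$n_features %||% length(space$feature_ids)
  if (n_features != length(space$feature_ids)) {
    stop_ccann(sprintf("config expects %d features but the feature space has %d",
                       n_features, length(space$feature_ids)),
               class = "ccann_shape_error")
  }
  n_classes <- length(space$state_names)
  if (n_classes < 2) {
    stop_ccann("need at least 2 states", class = "ccann_invalid_parameter")
  }
  if (n_classes != config$n_classes) {
    config$n_classes <- n_classes
    if (!(config$hidden1 > config$hidden2 && config$hidden2 > n_classes)) {
      stop_ccann("layer sizes must funnel: hidden1 > hidden2 > n_classes",
                 class = "ccann_invalid_parameter")
    }
  }
  config$n_features <- n_features
  weights <- withr::with_seed(
    config$seed,
    nn_init(n_features, config$hidden1, config$hidden2, n_classes)
  )
  structure(
    list(config = config, feature_space = space, weights = weights,
         trained = FALSE, training_history = tibble()),
    class = "cc_classifier"
  )
}

aligned_values <- function(data, space) {
  x <- if (inherits(data, "cc_aligned")) data$values else data
  if (!is.matrix(x)) stop_ccann("expected an aligned cells x features matrix",
                                class = "ccann_shape_error")
  if (ncol(x) != length(space$feature_ids)) {
    stop_ccann(sprintf("input has %d features but the model expects %d",
                       ncol(x), length(space$feature_ids)),
               class = "ccann_shape_error")
  }
  x
}

#' Train the cell-cycle classifier
#'
#' Runs `rounds` consecutive repeats of `epochs_per_round` epochs of
#' minibatch SGD on categorical cross-entropy, carrying weights across
#' rounds. Each round redraws a random 80/20 (by default) train/holdout
#' partition; the held-out fraction is only used to record per-epoch loss and
#' accuracy. Cells are reshuffled every epoch; dropout is active only during
#' training; class proportions are left as-is (no rebalancing or class
#' weights). Deterministic under `config$seed`.
#'
#' @param model An untrained (or trained) `cc_classifier`.
#' @param data A `cc_aligned` or cells x features matrix in feature order.
#' @param labels Per-cell state names; every label must be in the model's
#'   vocabulary and every class needs at least 2 cells.
#' @return The trained `cc_classifier`, with `training_history` holding one
#'   row per (round, epoch): holdout loss and accuracy.
#' @export
train_classifier <- function(model, data, labels) {
  stopifnot(inherits(model, "cc_classifier"))
  cfg <- model$config
  space <- model$feature_space
  x <- aligned_values(data, space)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) {
    stop_ccann("`labels` length must match the number of cells",
               class = "ccann_shape_error")
  }
  bad <- setdiff(unique(labels), space$state_names)
  if (length(bad)) {
    stop_ccann(sprintf("label(s) outside the state vocabulary: %s",
                       paste(bad, collapse = ", ")))
  }
  tab <- table(factor(labels, levels = space$state_names))
  if (any(tab > 0 & tab < 2)) {
    stop_ccann(sprintf("class(es) with fewer than 2 cells: %s",
                       paste(names(tab)[tab > 0 & tab < 2], collapse = ", ")))
  }
  y_idx <- match(labels, space$state_names)
  k <- length(space$state_names)
  n <- nrow(x)

  withr::with_seed(cfg$seed, {
    w <- model$weights
    v <- nn_zero_like(w)
    history <- vector("list", cfg$rounds * cfg$epochs_per_round)
    h_i <- 0L
    for (round in seq_len(cfg$rounds)) {
      holdout <- sample.int(n, size = max(1L, round(cfg$holdout_fraction * n)))
      train_idx <- setdiff(seq_len(n), holdout)
      x_ho <- x[holdout, , drop = FALSE]
      y_ho <- y_idx[holdout]
      for (epoch in seq_len(cfg$epochs_per_round)) {
        order_idx <- sample(train_idx)
        starts <- seq(1L, length(order_idx), by = cfg$batch_size)
        for (s in starts) {
          b_idx <- order_idx[s:min(s + cfg$batch_size - 1L, length(order_idx))]
          xb <- x[b_idx, , drop = FALSE]
          yb <- y_idx[b_idx]
          fw <- nn_forward_train(w, xb, cfg$dropout_rate)
          y1 <- matrix(0, nrow = length(b_idx), ncol = k)
          y1[cbind(seq_along(b_idx), yb)] <- 1
          g <- nn_backward(w, xb, y1, fw)
          upd <- nn_sgd_step(w, v, g, cfg$learning_rate, cfg$momentum)
          w <- upd$w
          v <- upd$v
        }
        p_ho <- nn_forward(w, x_ho)
        h_i <- h_i + 1L
        history[[h_i]] <- tibble(
          round = round, epoch = epoch,
          holdout_loss = nn_cross_entropy(p_ho, y_ho),
          holdout_accuracy = nn_accuracy(p_ho, y_ho)
        )
      }
    }
    # drop dimnames picked up from the input matrix: weights are positional
    model$weights <- lapply(w, function(m) {
      if (is.matrix(m)) dimnames(m) <- NULL else names(m) <- NULL
      m
    })
    model$trained <- TRUE
    model$training_history <- dplyr::bind_rows(history)
    model
  })
}

#' Class likelihoods for new cells
#'
#' Forward pass of the trained network with dropout disabled: every row of
#' the result is a softmax probability vector over the state vocabulary
#' (sums to 1 within 1e-6). Deterministic.
#'
#' @param model A trained `cc_classifier`.
#' @param data A `cc_aligned` or cells x features matrix in feature order.
#' @return An object of class `cc_likelihood`: list with `values` (cells x
#'   states matrix), `state_names`, `cell_ids`.
#' @export
predict_likelihoods <- function(model, data) {
  stopifnot(inherits(model, "cc_classifier"))
  if (!model$trained) {
    rlang::warn("model has not been trained; likelihoods come from initial weights")
  }
  x <- aligned_values(data, model$feature_space)
  p <- nn_forward(model$weights, x)
  colnames(p) <- model$feature_space$state_names
  rownames(p) <- rownames(x)
  structure(
    list(values = p, state_names = model$feature_space$state_names,
         cell_ids = rownames(x) %||% as.character(seq_len(nrow(x)))),
    class = "cc_likelihood"
  )
}

#' Convert likelihoods to state assignments with threshold rejection
#'
#' Each cell gets the state with the maximum likelihood if that likelihood is
#' at least `threshold`, otherwise the label `"Unknown"`. Ties are broken in
#' favor of the first state in the vocabulary order (a message reports how
#' many ties occurred). `threshold = 0` therefore never produces Unknowns.
#'
#' @param lik A `cc_likelihood` from [predict_likelihoods()].
#' @param threshold Minimum winning likelihood, in `[0, 1]` (default 0.5).
#' @return A tibble of class `cc_assignment` with columns `cell_id`, `label`,
#'   `max_likelihood`, `threshold`.
#' @export
assign_states <- function(lik, threshold = 0.5) {
  stopifnot(inherits(lik, "cc_likelihood"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    stop_ccann("`threshold` must be in [0, 1]", class = "ccann_invalid_parameter")
  }
  p <- lik$values
  win <- max.col(p, ties.method = "first")
  n_ties <- sum(rowSums(p == p[cbind(seq_len(nrow(p)), win)]) > 1)
  if (n_ties > 0) {
    rlang::inform(sprintf(
      "%d tie(s) in maximum likelihood broken by vocabulary order", n_ties))
  }
  max_lik <- p[cbind(seq_len(nrow(p)), win)]
  label <- ifelse(max_lik < threshold, "Unknown", lik$state_names[win])
  out <- tibble(cell_id = lik$cell_ids, label = label,
                max_likelihood = max_lik, threshold = threshold)
  class(out) <- c("cc_assignment", class(out))
  out
}

#' Collapse Neural G0, G1 and Late G1 into a single G0/G1 label
#'
#' In non-neuroepithelial cell types the classifier's misassignments are
#' confined to the Neural G0 / G1 / Late G1 trio, so merging them into one
#' `"G0/G1"` label gives a conservative coarse assignment. All other labels
#' (including `"Unknown"`) pass through unchanged; the operation is
#' idempotent.
#'
#' @param assign A `cc_assignment` tibble, or a character vector of labels.
#' @return Same shape as the input with collapsed labels.
#' @export
collapse_g0g1 <- function(assign) {
  collapse <- function(l) ifelse(l %in% c("Neural G0", "G1", "Late G1"),
                                 "G0/G1", l)
  if (is.character(assign)) return(collapse(assign))
  stopifnot(is.data.frame(assign), "label" %in% names(assign))
  assign$label <- collapse(assign$label)
  assign
}

CCANN_MODEL_FORMAT <- 1L

#' Save / load a trained classifier
#'
#' The archive is a single JSON file: a header (format version, config, state
#' vocabulary, feature ids, marker sets) plus full-precision weight arrays.
#' Round-tripping preserves config, feature space and weights bit-for-bit, so
#' a loaded model predicts identically to the saved one. Truncated or foreign
#' files and format-version mismatches raise explicit errors.
#'
#' @param model A `cc_classifier`.
#' @param path File path for the archive.
#' @return `save_classifier()`: `path`, invisibly. `load_classifier()`: the
#'   restored `cc_classifier`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "cc_classifier"))
  payload <- list(
    format = "ccann_model",
    format_version = CCANN_MODEL_FORMAT,
    config = unclass(model$config),
    feature_space = list(
      feature_ids = model$feature_space$feature_ids,
      state_names = model$feature_space$state_names,
      marker_sets = model$feature_space$marker_sets,
      id_type = model$feature_space$id_type
    ),
    trained = model$trained,
    training_history = as.list(model$training_history),
    # raw little-endian doubles, base64-wrapped: lossless round-trip
    weights = lapply(model$weights, function(m) {
      list(dim = if (is.matrix(m)) dim(m) else length(m),
           data = jsonlite::base64_enc(writeBin(as.vector(m), raw(),
                                                size = 8, endian = "little")))
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) {
    stop_ccann(sprintf("no such model archive: %s", path), class = "ccann_io_error")
  }
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop_ccann(sprintf("not a readable model archive (%s): %s",
                         conditionMessage(e), path),
                 class = "ccann_format_error")
    }
  )
  if (!identical(payload$format, "ccann_model")) {
    stop_ccann("file is not a ccann model archive", class = "ccann_format_error")
  }
  if (!identical(as.integer(payload$format_version), CCANN_MODEL_FORMAT)) {
    stop_ccann(sprintf("model archive format version %s is not supported (expected %d)",
                       payload$format_version, CCANN_MODEL_FORMAT),
               class = "ccann_format_error")
  }
  cfg <- payload$config
  config <- model_config(
    n_features = cfg$n_features, hidden1 = cfg$hidden1, hidden2 = cfg$hidden2,
    n_classes = cfg$n_classes, dropout_rate = cfg$dropout_rate,
    epochs_per_round = cfg$epochs_per_round, rounds = cfg$rounds,
    holdout_fraction = cfg$holdout_fraction, learning_rate = cfg$learning_rate,
    momentum = cfg$momentum, batch_size = cfg$batch_size, seed = cfg$seed
  )
  fs <- payload$feature_space
  marker_sets <- fs$marker_sets
  if (length(marker_sets) == 0) marker_sets <- NULL
  space <- feature_space(fs$feature_ids, fs$state_names, marker_sets,
                         id_maps = list(), id_type = fs$id_type)
  weights <- lapply(payload$weights, function(wp) {
    vals <- readBin(jsonlite::base64_dec(wp$data), what = "double",
                    n = prod(wp$dim), size = 8, endian = "little")
    if (length(wp$dim) == 2) matrix(vals, nrow = wp$dim[1], ncol = wp$dim[2])
    else vals
  })
  structure(
    list(config = config, feature_space = space, weights = weights,
         trained = isTRUE(payload$trained),
         training_history = as_tibble(payload$training_history)),
    class = "cc_classifier"
  )
}

#' @export
print.cc_classifier <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<cc_classifier> %d features -> %d -> %d -> %d states (%s; %s parameters)\n",
    cfg$n_features, cfg$hidden1, cfg$hidden2, length(x$feature_space$state_names),
    if (x$trained) "trained" else "untrained",
    format(nn_param_count(x$weights), big.mark = ",")))
  invisible(x)
}

#' Tidy the training history of a classifier
#'
#' @param x A `cc_classifier`.
#' @param ... Unused.
#' @return A tibble with one row per (round, epoch): holdout loss/accuracy.
#' @method tidy cc_classifier
#' @export
tidy.cc_classifier <- function(x, ...) x$training_history

#' One-row summary of a classifier
#'
#' @param x A `cc_classifier`.
#' @param ... Unused.
#' @return A one-row tibble: layer sizes, parameter count, training schedule,
#'   final holdout accuracy (NA if untrained).
#' @method glance cc_classifier
#' @export
glance.cc_classifier <- function(x, ...) {
  hist <- x$training_history
  tibble(
    n_features = x$config$n_features,
    hidden1 = x$config$hidden1,
    hidden2 = x$config$hidden2,
    n_states = length(x$feature_space$state_names),
    n_params = nn_param_count(x$weights),
    rounds = x$config$rounds,
    epochs_per_round = x$config$epochs_per_round,
    trained = x$trained,
    final_holdout_accuracy = if (nrow(hist)) hist$holdout_accuracy[nrow(hist)]
                             else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a likelihood matrix into long form
#'
#' @param x A `cc_likelihood`.
#' @param ... Unused.
#' @return A tibble with columns `cell_id`, `state`, `likelihood`.
#' @method tidy cc_likelihood
#' @export
tidy.cc_likelihood <- function(x, ...) {
  as_tibble(x$values, rownames = "cell_id") |>
    tidyr::pivot_longer(-"cell_id", names_to = "state",
                        values_to = "likelihood")
}

#' @export
print.cc_likelihood <- function(x, ...) {
  cat(sprintf("<cc_likelihood> %d cells x %d states\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
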