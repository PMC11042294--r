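#' Permutation feature importance
#'
#' Quantifies each input gene's contribution to each state's likelihood:
#' baseline likelihoods are computed once; then, for each feature, its column
#' is permuted across cells (one seeded permutation per repeat), likelihoods
#' are recomputed, and the mean over cells of (permuted - baseline)
#' likelihood is recorded per state. A negative mean delta means the feature
#' was important for that state. When `restrict_to_labels` is supplied, the
#' mean for each state is taken only over cells carrying that label (the
#' default mode for labeled data, since importance for a state is best read
#' from cells known to be in it); otherwise over all cells.
#'
#' Permuting a feature only changes the first-layer pre-activations by a
#' rank-one update, which the implementation exploits; the result is exactly
#' equal to a full forward pass on the permuted matrix.
#'
#' @param model A trained `cc_classifier`.
#' @param data A `cc_aligned` or cells x features matrix in feature order.
#' @param seed Seed for the permutations.
#' @param restrict_to_labels Optional per-cell state names.
#' @param repeats Number of permutations averaged per feature (default 1).
#' @return A tibble of class `cc_importance` with columns `gene`, `state`,
#'   `mean_delta_likelihood`, `n_cells_evaluated`.
#' @export
permutation_importance <- function(model, data, seed = 1L,
                                   restrict_to_labels = NULL, repeats = 1L) {
  stopifnot(inherits(model, "cc_classifier"))
  repeats <- check_count(repeats, "repeats")
  x <- aligned_values(data, model$feature_space)
  states <- model$feature_space$state_names
  genes <- model$feature_space$feature_ids
  w <- model$weights
  n <- nrow(x)

  if (!is.null(restrict_to_labels)) {
    restrict_to_labels <- as.character(restrict_to_labels)
    if (length(restrict_to_labels) != n) {
      stop_ccann("`restrict_to_labels` length must match the number of cells",
                 class = "ccann_shape_error")
    }
    cell_sets <- lapply(states, function(s) which(restrict_to_labels == s))
  } else {
    cell_sets <- rep(list(seq_len(n)), length(states))
  }
  n_eval <- vapply(cell_sets, length, integer(1))

  a1 <- add_bias(x %*% w$W1, w$b1)   # cached first-layer pre-activations
  p0 <- forward_from_a1(w, a1)

  deltas <- matrix(0, nrow = length(genes), ncol = length(states))
  withr::with_seed(seed, {
    for (j in seq_along(genes)) {
      acc <- numeric(length(states))
      for (r in seq_len(repeats)) {
        perm <- sample.int(n)
        dx <- x[perm, j] - x[, j]
        if (all(dx == 0)) next    # constant feature: permutation is identity
        p1 <- forward_from_a1(w, a1 + tcrossprod(dx, w$W1[j, ]))
        d <- p1 - p0
        acc <- acc + vapply(seq_along(states), function(k) {
          cells <- cell_sets[[k]]
          if (length(cells) == 0) NA_real_ else mean(d[cells, k])
        }, numeric(1))
      }
      deltas[j, ] <- acc / repeats
    }
  })
  out <- tibble(
    gene = rep(genes, times = length(states)),
    state = rep(states, each = length(genes)),
    mean_delta_likelihood = as.vector(deltas),
    n_cells_evaluated = rep(n_eval, each = length(genes))
  )
  class(out) <- c("cc_importance", class(out))
  out
}

# Forward pass given first-layer pre-activations (inference mode).
forward_from_a1 <- function(w, a1) {
  h1 <- pmax(a1, 0)
  h2 <- pmax(add_bias(h1 %*% w$W2, w$b2), 0)
  softmax_rows(add_bias(h2 %*% w$W3, w$b3))
}

#' Top features for one state
#'
#' Ranks genes by ascending mean delta likelihood (most negative = most
#' important); ties are broken alphabetically, so the ranking is stable.
#'
#' @param table A `cc_importance` tibble.
#' @param state State to rank features for.
#' @param n Number of features to return (the full ranking if fewer exist).
#' @return A character vector of gene names, most important first.
#' @export
top_features <- function(table, state, n = 15L) {
  stopifnot(is.data.frame(table),
            all(c("gene", "state", "mean_delta_likelihood") %in% names(table)))
  if (!state %in% table$state) {
    stop_ccann(sprintf("state '%s' not present in the importance table", state),
               class = "ccann_unknown_state")
  }
  rows <- table[table$state == state, ]
  rows <- rows[order(rows$mean_delta_likelihood, rows$gene), ]
  head(rows$gene, n)
}
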