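#' Parameters for the labeled synthetic scRNA-seq generator
#'
#' Defines the planted ground truth used to emulate a labeled multi-state
#' scRNA-seq experiment: each cell belongs to one of `n_states` cell-cycle
#' states, each state up-regulates a disjoint block of `markers_per_state`
#' marker genes by `marker_log2fc` on the log2 scale, counts are negative
#' binomial with a common dispersion, and observed counts are independently
#' zeroed with probability `dropout_rate` to mimic transcript dropout.
#'
#' A single `seed` drives the whole generator: state assignment, counts, and
#' dropout are drawn from one random stream in that fixed order, so identical
#' parameters reproduce identical matrices.
#'
#' @param n_states Number of planted states.
#' @param state_names Ordered state labels; defaults to the seven-state
#'   cell-cycle vocabulary (Neural G0, G1, Late G1, S, S/G2, G2/M, M/Early G1).
#' @param state_proportions Simplex weights per state (must sum to 1, all > 0).
#' @param n_genes Total number of genes.
#' @param markers_per_state Number of marker genes planted per state; marker
#'   blocks are disjoint across states, so
#'   `markers_per_state * n_states <= n_genes`.
#' @param marker_log2fc Planted effect size: marker genes have negative
#'   binomial mean `baseline_mean * 2^marker_log2fc` in their own state.
#' @param baseline_mean Negative-binomial mean of non-marker genes.
#' @param dispersion Negative-binomial size (inverse overdispersion); the
#'   count variance is `mu + mu^2 / dispersion`.
#' @param dropout_rate Probability that an observed count is forced to zero.
#' @param seed Integer seed for the generator's single random stream.
#'
#' @return An object of class `cc_synthetic_params`.
#' @seealso [simulate_dataset()], [simulate_bulk_signature()]
#' @export
synthetic_params <- function(n_states = 7L,
                             state_names = CC_STATES,
                             state_proportions = rep(1 / n_states, n_states),
                             n_genes = 1000L,
                             markers_per_state = 15L,
                             marker_log2fc = 2,
                             baseline_mean = 5,
                             dispersion = 2,
                             dropout_rate = 0.2,
                             seed = 1L) {
  n_states <- check_count(n_states, "n_states", min = 2L)
  n_genes <- check_count(n_genes, "n_genes")
  markers_per_state <- check_count(markers_per_state, "markers_per_state")
  if (length(state_names) != n_states || anyDuplicated(state_names)) {
    stop_ccann("`state_names` must hold `n_states` unique labels",
               class = "ccann_invalid_parameter")
  }
  if (length(state_proportions) != n_states ||
      any(state_proportions <= 0) ||
      abs(sum(state_proportions) - 1) > 1e-12) {
    stop_ccann("`state_proportions` must be positive and sum to 1 (within 1e-12)",
               class = "ccann_invalid_parameter")
  }
  if (markers_per_state * n_states > n_genes) {
    stop_ccann("markers_per_state * n_states must not exceed n_genes",
               class = "ccann_invalid_parameter")
  }
  if (marker_log2fc <= 0 || baseline_mean <= 0 || dispersion <= 0) {
    stop_ccann("`marker_log2fc`, `baseline_mean` and `dispersion` must be positive",
               class = "ccann_invalid_parameter")
  }
  check_prob(dropout_rate, "dropout_rate")
  structure(
    list(
      n_states = n_states,
      state_names = as.character(state_names),
      state_proportions = as.numeric(state_proportions),
      n_genes = n_genes,
      markers_per_state = markers_per_state,
      marker_log2fc = marker_log2fc,
      baseline_mean = baseline_mean,
      dispersion = dispersion,
      dropout_rate = dropout_rate,
      seed = as.integer(seed)
    ),
    class = "cc_synthetic_params"
  )
}

gene_names <- function(n_genes) {
  sprintf("g%05d", seq_len(n_genes))
}

# Disjoint marker blocks: the first markers_per_state * n_states genes,
# assigned to states in state_names order.
marker_sets_from_params <- function(params) {
  ids <- gene_names(params$n_genes)
  sets <- split(
    ids[seq_len(params$markers_per_state * params$n_states)],
    rep(seq_len(params$n_states), each = params$markers_per_state)
  )
  setNames(sets, params$state_names)
}

#' Generate a labeled synthetic scRNA-seq count matrix
#'
#' Draws per-cell states from `state_proportions`, then negative-binomial
#' counts (marker genes at `baseline_mean * 2^marker_log2fc` in their own
#' state, `baseline_mean` elsewhere), then independent dropout. All three
#' draws come from one stream seeded by `params$seed`, in that fixed order.
#'
#' @param params A [synthetic_params()] object.
#' @param n_cells Number of cells to generate.
#'
#' @return An object of class `cc_dataset`: a list with `counts` (genes x
#'   cells integer matrix with gene/cell dimnames), `labels` (per-cell state),
#'   `marker_sets` (named list of planted marker genes per state), and
#'   `params` (the generating truth).
#' @export
simulate_dataset <- function(params, n_cells) {
  if (!inherits(params, "cc_synthetic_params")) {
    stop_ccann("`params` must come from synthetic_params()",
               class = "ccann_invalid_parameter")
  }
  n_cells <- check_count(n_cells, "n_cells")
  marker_sets <- marker_sets_from_params(params)
  genes <- gene_names(params$n_genes)

  withr::with_seed(params$seed, {
    state_idx <- sample.int(params$n_states, n_cells, replace = TRUE,
                            prob = params$state_proportions)
    mu <- build_mean_matrix(params, marker_sets, state_idx)
    counts <- matrix(
      rnbinom(length(mu), size = params$dispersion, mu = as.vector(mu)),
      nrow = params$n_genes, ncol = n_cells
    )
    if (params$dropout_rate > 0) {
      keep <- rbinom(length(counts), 1L, 1 - params$dropout_rate)
      counts <- counts * keep
    }
    dimnames(counts) <- list(genes, sprintf("cell%06d", seq_len(n_cells)))
    structure(
      list(
        counts = counts,
        labels = params$state_names[state_idx],
        marker_sets = marker_sets,
        params = params
      ),
      class = "cc_dataset"
    )
  })
}

# Genes x cells matrix of NB means for ordinary (single-state) cells.
build_mean_matrix <- function(params, marker_sets, state_idx) {
  mu <- matrix(params$baseline_mean, nrow = params$n_genes,
               ncol = length(state_idx))
  hi <- params$baseline_mean * 2^params$marker_log2fc
  marker_rows <- lapply(params$state_names, function(s) {
    match(marker_sets[[s]], gene_names(params$n_genes))
  })
  for (s in seq_len(params$n_states)) {
    cells <- which(state_idx == s)
    if (length(cells)) mu[marker_rows[[s]], cells] <- hi
  }
  mu
}

#' Generate boundary cells between pairs of cell-cycle states
#'
#' Emulates transcriptionally ambiguous cells (e.g. doublets or cells
#' transitioning between states): each cell has the marker blocks of *two*
#' distinct states elevated simultaneously, and its reference label is drawn
#' at random from that pair. A trained classifier concentrates such a cell's
#' likelihood on the two involved states; note that a strongly fitted
#' classifier may still commit confidently to one of the pair. Cells whose
#' classifications are genuinely uncertain are better emulated by
#' [simulate_dataset()] with a reduced `marker_log2fc`.
#'
#' @param params A [synthetic_params()] object.
#' @param n_cells Number of boundary cells.
#' @param seed Seed for this draw (independent of `params$seed`).
#'
#' @return A `cc_dataset` whose `labels` are the noisy reference labels; the
#'   true state pair of each cell is stored in the `state_pairs` element
#'   (an `n_cells` x 2 character matrix).
#' @export
simulate_boundary_cells <- function(params, n_cells, seed = params$seed + 1L) {
  if (!inherits(params, "cc_synthetic_params")) {
    stop_ccann("`params` must come from synthetic_params()",
               class = "ccann_invalid_parameter")
  }
  n_cells <- check_count(n_cells, "n_cells")
  marker_sets <- marker_sets_from_params(params)
  genes <- gene_names(params$n_genes)
  hi <- params$baseline_mean * 2^params$marker_log2fc

  withr::with_seed(seed, {
    pair_idx <- t(replicate(n_cells, sample.int(params$n_states, 2L)))
    mu <- matrix(params$baseline_mean, nrow = params$n_genes, ncol = n_cells)
    for (i in seq_len(n_cells)) {
      rows <- match(unlist(marker_sets[pair_idx[i, ]]), genes)
      mu[rows, i] <- hi
    }
    counts <- matrix(
      rnbinom(length(mu), size = params$dispersion, mu = as.vector(mu)),
      nrow = params$n_genes, ncol = n_cells
    )
    if (params$dropout_rate > 0) {
      keep <- rbinom(length(counts), 1L, 1 - params$dropout_rate)
      counts <- counts * keep
    }
    dimnames(counts) <- list(genes, sprintf("bcell%05d", seq_len(n_cells)))
    noisy <- params$state_names[pair_idx[cbind(seq_len(n_cells),
                                               sample(c(1L, 2L), n_cells, TRUE))]]
    structure(
      list(
        counts = counts,
        labels = noisy,
        marker_sets = marker_sets,
        params = params,
        state_pairs = matrix(params$state_names[pair_idx], ncol = 2L)
      ),
      class = "cc_dataset"
    )
  })
}

#' Simulate a bulk expression signature for one planted state
#'
#' Emulates bulk RNA-seq of a sorted subpopulation: each replicate is the
#' gene-wise mean of a resampled subset of that state's cells, scaled by
#' `depth_factor` (bulk libraries are deeper than single cells) with small
#' multiplicative log-normal noise.
#'
#' @param dataset A `cc_dataset` from [simulate_dataset()].
#' @param state State name whose signature to build.
#' @param n_replicates Number of bulk replicates (columns).
#' @param subsample_fraction Fraction of the state's cells resampled (with
#'   replacement) per replicate.
#' @param depth_factor Multiplicative depth scaling applied to the mean.
#' @param noise_sd Standard deviation of the multiplicative log-normal noise.
#' @param seed Seed for the resampling and noise.
#'
#' @return A genes x replicates numeric matrix in the dataset's gene order,
#'   with columns `rep1`, `rep2`, ...
#' @export
simulate_bulk_signature <- function(dataset, state, n_replicates = 2L,
                                    subsample_fraction = 0.7,
                                    depth_factor = 10,
                                    noise_sd = 0.05,
                                    seed = dataset$params$seed + 2L) {
  stopifnot(inherits(dataset, "cc_dataset"))
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (!state %in% dataset$params$state_names) {
    stop_ccann(sprintf("unknown state '%s'", state), class = "ccann_unknown_state")
  }
  cells <- which(dataset$labels == state)
  if (length(cells) == 0) {
    stop_ccann(sprintf("state '%s' has no cells in this dataset", state),
               class = "ccann_unknown_state")
  }
  withr::with_seed(seed, {
    sig <- vapply(seq_len(n_replicates), function(r) {
      idx <- sample(cells, size = max(1L, round(subsample_fraction * length(cells))),
                    replace = TRUE)
      m <- rowMeans(dataset$counts[, idx, drop = FALSE]) * depth_factor
      m * exp(rnorm(nrow(dataset$counts), 0, noise_sd))
    }, numeric(nrow(dataset$counts)))
    dimnames(sig) <- list(rownames(dataset$counts),
                          paste0("rep", seq_len(n_replicates)))
    sig
  })
}

#' Write a synthetic dataset as a 10x-style MTX triplet plus labels
#'
#' Writes `matrix.mtx`, `features.tsv` (id and symbol columns), and
#' `barcodes.tsv` in MatrixMarket/10x convention (genes x cells), plus
#' `labels.tsv` with columns `barcode` and `state`.
#'
#' @param dataset A `cc_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_mtx <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(dataset$counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(
    tibble(id = rownames(dataset$counts), symbol = rownames(dataset$counts)),
    file.path(dir, "features.tsv"), col_names = FALSE
  )
  readr::write_tsv(tibble(barcode = colnames(dataset$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = colnames(dataset$counts),
                          state = dataset$labels),
                   file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' @export
print.cc_dataset <- function(x, ...) {
  cat(sprintf("<cc_dataset> %d genes x %d cells, %d states\n",
              nrow(x$counts), ncol(x$counts), x$params$n_states))
  print(table(x$labels))
  invisible(x)
}
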