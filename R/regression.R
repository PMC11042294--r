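#' Module score for a gene set
#'
#' Per-cell mean expression of a gene set minus the mean of
#' expression-matched control genes: all genes are binned into `n_bins`
#' equal-frequency bins by their average expression, each set gene draws
#' `n_ctrl` control genes from its own bin (seeded), and the score is
#' `mean(set genes) - mean(control pool)` per cell. Matching controls on
#' average expression removes depth/abundance trends from the score.
#'
#' @param expr Normalized genes x cells matrix.
#' @param gene_set Character vector of set genes (at least one must be
#'   present in `expr`).
#' @param n_bins Number of expression-average bins (default 24).
#' @param n_ctrl Controls drawn per set gene (default 100).
#' @param seed Seed for the control draws.
#' @return A named per-cell numeric vector of scores.
#' @export
module_score <- function(expr, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  x <- as_gene_matrix(expr)
  if (is.null(rownames(x))) stop_ccann("expression matrix must have gene rownames")
  set_genes <- intersect(unique(gene_set), rownames(x))
  if (length(set_genes) == 0) {
    stop_ccann("none of the gene_set genes are present in the matrix")
  }
  n_bins <- check_count(n_bins, "n_bins")
  n_ctrl <- check_count(n_ctrl, "n_ctrl")
  avg <- rowMeans(x)
  bin <- dplyr::ntile(rank(avg, ties.method = "first"), min(n_bins, nrow(x)))
  names(bin) <- rownames(x)

  # controls come from the same expression bin but never from the set itself
  ctrl_pool <- withr::with_seed(seed, {
    unique(unlist(lapply(set_genes, function(g) {
      mates <- setdiff(names(bin)[bin == bin[[g]]], set_genes)
      if (length(mates) == 0) {
        stop_ccann("no control genes available outside the gene set")
      }
      sample(mates, size = n_ctrl, replace = length(mates) < n_ctrl)
    })))
  })
  colMeans(x[set_genes, , drop = FALSE]) -
    colMeans(x[ctrl_pool, , drop = FALSE])
}

#' Module scores for several states at once
#'
#' Convenience wrapper building one [module_score()] column per marker set.
#'
#' @param expr Normalized genes x cells matrix.
#' @param marker_sets Named list (state -> marker genes), e.g. from a
#'   `cc_dataset` or `cc_feature_space`.
#' @inheritParams module_score
#' @return A cells x states numeric matrix of scores.
#' @export
module_scores <- function(expr, marker_sets, n_bins = 24L, n_ctrl = 100L,
                          seed = 1L) {
  stopifnot(is.list(marker_sets), !is.null(names(marker_sets)))
  out <- vapply(seq_along(marker_sets), function(i) {
    module_score(expr, marker_sets[[i]], n_bins = n_bins, n_ctrl = n_ctrl,
                 seed = derive_seed(seed, names(marker_sets)[i]))
  }, numeric(ncol(as_gene_matrix(expr))))
  colnames(out) <- names(marker_sets)
  out
}

#' Regress covariates out of an expression matrix
#'
#' Ordinary least squares of every gene on the covariate columns (with
#' intercept); the returned matrix holds the residuals, preserving gene and
#' cell order. Residuals are orthogonal to every covariate, and the
#' operation is a projection (applying it twice changes nothing).
#'
#' @param expr Normalized genes x cells matrix.
#' @param covariates Cells x k numeric matrix (e.g. [module_scores()]).
#' @return Genes x cells residual matrix.
#' @export
regress_out <- function(expr, covariates) {
  x <- as_gene_matrix(expr)
  cov <- as.matrix(covariates)
  if (nrow(cov) != ncol(x)) {
    stop_ccann("covariate rows must match the number of cells",
               class = "ccann_shape_error")
  }
  cov <- cov[, colSums(abs(cov)) > 0, drop = FALSE]   # all-zero scores carry no signal
  design <- cbind(`(Intercept)` = 1, cov)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    stop_ccann(
      "covariates are rank-deficient; drop a collinear score and retry",
      class = "ccann_invalid_parameter")
  }
  res <- t(qr.resid(qr_d, t(x)))
  dimnames(res) <- dimnames(x)
  res
}

#' Variance explained by the first principal component of a gene set
#'
#' PCA of the mean-centered cells x set-genes submatrix; returns the
#' fraction of total variance carried by PC1. Co-expressed sets (e.g.
#' cycling marker genes before regression) give values near 1; independent
#' noise gives about `1 / n_genes`.
#'
#' @param expr Genes x cells matrix.
#' @param gene_set Genes to extract (at least 2 must be present).
#' @return The PC1 variance fraction, a scalar in (0, 1].
#' @export
pc1_variance_explained <- function(expr, gene_set) {
  x <- as_gene_matrix(expr)
  genes <- intersect(unique(gene_set), rownames(x))
  if (length(genes) < 2) stop_ccann("need at least 2 set genes present")
  if (ncol(x) < 3) stop_ccann("need at least 3 cells")
  sub <- t(x[genes, , drop = FALSE])          # cells x genes
  sub <- sweep(sub, 2, colMeans(sub))
  ev <- eigen(crossprod(sub), symmetric = TRUE, only.values = TRUE)$values
  tot <- sum(ev)
  if (tot <= 0) stop_ccann("gene-set submatrix is constant")
  ev[1] / tot
}

#' Empirical test of gene-set co-expression
#'
#' Compares the observed PC1 variance fraction of `gene_set` to that of
#' `n_random` random gene sets of the same size drawn uniformly without
#' replacement from all genes in `expr`. The one-sided empirical p-value
#' uses the add-one convention `p = (1 + #{random >= observed}) / (1 +
#' n_random)`, so it is never exactly zero. After successful cell-cycle
#' regression the set should look like a random set (p > 0.05).
#'
#' @param expr Genes x cells matrix.
#' @param gene_set Genes whose co-expression is tested.
#' @param n_random Number of random sets (default 1000).
#' @param seed Seed for the random draws.
#' @return A scalar empirical p-value with attributes `observed` (the PC1
#'   variance fraction) and `n_random`.
#' @export
empirical_variance_test <- function(expr, gene_set, n_random = 1000L,
                                    seed = 1L) {
  n_random <- check_count(n_random, "n_random")
  x <- as_gene_matrix(expr)
  genes <- intersect(unique(gene_set), rownames(x))
  if (nrow(x) < 2 * length(genes)) {
    stop_ccann("gene universe must be at least twice the gene-set size")
  }
  observed <- pc1_variance_explained(x, genes)
  rand <- withr::with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      pc1_variance_explained(x, sample(rownames(x), length(genes)))
    }, numeric(1))
  })
  p <- (1 + sum(rand >= observed)) / (1 + n_random)
  attr(p, "observed") <- observed
  attr(p, "n_random") <- n_random
  p
}

#' Before/after report for cell-cycle signal removal
#'
#' Runs [empirical_variance_test()] on the same gene set in the matrices
#' before and after [regress_out()], summarizing whether the cycling
#' signature was removed (success: significant before, non-significant
#' after).
#'
#' @param expr_before,expr_after Genes x cells matrices.
#' @param gene_set Genes whose co-expression is tested.
#' @inheritParams empirical_variance_test
#' @return A one-row tibble: `variance_explained_before/after`,
#'   `empirical_p_before/after`, `n_random`.
#' @export
regression_report <- function(expr_before, expr_after, gene_set,
                              n_random = 1000L, seed = 1L) {
  p_before <- empirical_variance_test(expr_before, gene_set, n_random, seed)
  p_after <- empirical_variance_test(expr_after, gene_set, n_random, seed)
  tibble(
    variance_explained_before = attr(p_before, "observed"),
    variance_explained_after = attr(p_after, "observed"),
    empirical_p_before = as.numeric(p_before),
    empirical_p_after = as.numeric(p_after),
    n_random = n_random
  )
}
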