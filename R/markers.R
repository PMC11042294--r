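#' Find per-state marker genes
#'
#' One-vs-rest differential expression per state: a two-sided Wilcoxon
#' rank-sum test per gene (normal approximation with tie and continuity
#' correction, matching `stats::wilcox.test()`), Benjamini--Hochberg
#' adjustment across genes within each state, and a fold change computed on
#' de-logged means, `log2fc = log2((mean_in + eps) / (mean_out + eps))` with
#' `eps = 1e-9`. Only up-regulated genes passing both `logfc_min` and
#' `padj_max` are kept.
#'
#' @param expr Normalized genes x cells matrix (log1p scale unless
#'   `delog = FALSE`).
#' @param labels Per-cell state names; at least 2 states, each with at least
#'   3 cells.
#' @param logfc_min Minimum log2 fold change (default 0.25).
#' @param padj_max Maximum BH-adjusted p-value (default 0.05).
#' @param delog Apply `expm1()` before computing group means (use `FALSE`
#'   for data not on a log1p scale, e.g. Pearson residuals).
#' @return A tibble of class `cc_markers` with columns `gene`, `state`,
#'   `log2fc`, `p`, `p_adj`, `mean_in`, `mean_out`, ordered by state then
#'   adjusted p-value.
#' @export
find_state_markers <- function(expr, labels, logfc_min = 0.25,
                               padj_max = 0.05, delog = TRUE) {
  x <- as_gene_matrix(expr)
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) {
    stop_ccann("`labels` length must match the number of cells",
               class = "ccann_shape_error")
  }
  states <- unique(labels)
  if (length(states) < 2) stop_ccann("need at least 2 states")
  small <- states[vapply(states, function(s) sum(labels == s), numeric(1)) < 3]
  if (length(small)) {
    stop_ccann(sprintf("state(s) with fewer than 3 cells: %s",
                       paste(small, collapse = ", ")))
  }
  n <- ncol(x)
  # Per-gene ranks across cells (shared by all states) and tie correction.
  ranks <- t(apply(x, 1, rank))
  tie_term <- apply(x, 1, function(v) {
    t <- tabulate(match(v, unique(v)))
    sum(t^3 - t)
  })
  means_mat <- if (delog) expm1(x) else x
  eps <- 1e-9

  res <- lapply(states, function(s) {
    in_grp <- labels == s
    n1 <- sum(in_grp)
    n2 <- n - n1
    r1 <- rowSums(ranks[, in_grp, drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu_u <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    z_num <- u - mu_u
    z <- (z_num - sign(z_num) * 0.5) / sqrt(sigma2)
    p <- ifelse(sigma2 <= 0, 1, 2 * pnorm(-abs(z)))
    p <- pmin(p, 1)
    mean_in <- rowMeans(means_mat[, in_grp, drop = FALSE])
    mean_out <- rowMeans(means_mat[, !in_grp, drop = FALSE])
    tibble(
      gene = rownames(x) %||% as.character(seq_len(nrow(x))),
      state = s,
      log2fc = unname(log2((mean_in + eps) / (mean_out + eps))),
      p = unname(p),
      p_adj = unname(p.adjust(p, method = "BH")),
      mean_in = unname(mean_in),
      mean_out = unname(mean_out)
    )
  })
  out <- dplyr::bind_rows(res) |>
    dplyr::filter(.data$log2fc >= logfc_min, .data$p_adj <= padj_max) |>
    dplyr::arrange(match(.data$state, states), .data$p_adj, .data$gene)
  class(out) <- c("cc_markers", class(out))
  out
}

#' Hypergeometric overlap between two gene sets
#'
#' Upper-tail hypergeometric enrichment: the p-value is
#' `P(X >= n_overlap)` for `X ~ Hypergeometric(|universe|, |set_a|, |set_b|)`,
#' i.e. the chance that two sets of these sizes drawn from the universe share
#' at least the observed number of genes.
#'
#' @param set_a,set_b Gene sets (deduplicated); both must lie inside
#'   `universe`.
#' @param universe The gene universe the sets were drawn from.
#' @return A one-row tibble: `n_overlap`, `universe_size`, `size_a`,
#'   `size_b`, `p_value`.
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop_ccann("`universe` must be non-empty")
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  outside <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(outside)) {
    stop_ccann(sprintf("set element(s) outside the universe: %s",
                       paste(head(outside, 10), collapse = ", ")))
  }
  n_overlap <- length(intersect(set_a, set_b))
  p <- phyper(n_overlap - 1, length(set_a),
              length(universe) - length(set_a), length(set_b),
              lower.tail = FALSE)
  tibble(
    n_overlap = n_overlap,
    universe_size = length(universe),
    size_a = length(set_a),
    size_b = length(set_b),
    p_value = max(p, .Machine$double.xmin)
  )
}

#' Correlate single cells against bulk signature profiles
#'
#' Spearman rank correlation of each cell's expression vector against each
#' bulk replicate, restricted to an informative gene set: highly variable
#' genes of the single-cell data (top `n_hvg` by variance-to-mean ratio)
#' that exceed `bulk_min` counts in every bulk replicate, unioned with any
#' `extra_genes` (e.g. the classifier's input genes) present in the bulk
#' profiles.
#'
#' @param expr Normalized genes x cells matrix.
#' @param signature Genes x replicates bulk matrix (rownames = gene ids), or
#'   a single named vector.
#' @param n_hvg Number of highly variable genes to consider.
#' @param bulk_min Minimum bulk value required in all replicates.
#' @param extra_genes Genes always included when present in the bulk data.
#' @param min_shared Minimum usable gene count (error below this).
#' @return A tibble of class `cc_signature_cor` with columns `cell_id`,
#'   `replicate`, `rho`; the gene set used is in `attr(, "genes")`.
#' @export
correlate_signature <- function(expr, signature, n_hvg = 2000L, bulk_min = 10,
                                extra_genes = NULL, min_shared = 10L) {
  x <- as_gene_matrix(expr)
  if (is.null(dim(signature))) {
    signature <- matrix(signature, ncol = 1,
                        dimnames = list(names(signature), "rep1"))
  }
  if (is.null(rownames(x)) || is.null(rownames(signature))) {
    stop_ccann("both matrices need gene rownames")
  }
  gm <- rowMeans(x)
  gv <- apply(x, 1, var)
  vmr <- ifelse(gm > 0, gv / gm, 0)
  hvg <- rownames(x)[order(vmr, decreasing = TRUE)][seq_len(min(n_hvg, nrow(x)))]
  deep <- rownames(signature)[apply(signature > bulk_min, 1, all)]
  genes <- union(intersect(hvg, deep),
                 intersect(extra_genes, rownames(signature)))
  genes <- intersect(genes, rownames(x))
  if (length(genes) < min_shared) {
    stop_ccann(sprintf(
      "only %d usable shared gene(s) after filtering (need >= %d)",
      length(genes), min_shared))
  }
  rho <- cor(x[genes, , drop = FALSE], signature[genes, , drop = FALSE],
             method = "spearman")
  out <- as_tibble(rho, rownames = "cell_id") |>
    tidyr::pivot_longer(-"cell_id", names_to = "replicate", values_to = "rho")
  attr(out, "genes") <- genes
  class(out) <- c("cc_signature_cor", class(out))
  out
}

#' Call cells positive for a bulk signature
#'
#' A cell is signature-positive iff its Spearman correlation reaches `cutoff`
#' in *all* replicates (default 0.1, the rule used to define sorted-G0-like
#' cells).
#'
#' @param correlations A tibble from [correlate_signature()] (columns
#'   `cell_id`, `replicate`, `rho`).
#' @param cutoff Correlation cutoff applied per replicate.
#' @return A tibble with columns `cell_id`, `positive`.
#' @export
call_signature_positive <- function(correlations, cutoff = 0.1) {
  stopifnot(is.data.frame(correlations),
            all(c("cell_id", "rho") %in% names(correlations)))
  if (nrow(correlations) == 0) stop_ccann("need at least 1 replicate")
  correlations |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(positive = all(.data$rho >= cutoff), .groups = "drop")
}
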