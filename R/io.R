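#' Read a gene-by-cell expression matrix
#'
#' Reads either a 10x-style MTX triplet directory (`matrix.mtx[.gz]`,
#' `features.tsv[.gz]` or `genes.tsv[.gz]`, `barcodes.tsv[.gz]`) or a
#' delimited text matrix whose first column holds gene identifiers and whose
#' header row holds cell barcodes. Duplicate gene identifiers are summed
#' (with a warning) so that counts are preserved under collapsed annotations.
#'
#' @param path Directory (for `mtx_dir`) or file path (for `csv`/`tsv`).
#' @param format One of `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @param id_type Identifier system of the gene ids: `"symbol"` or
#'   `"ensembl"`. For MTX features files with two or more columns, column 1
#'   is taken as Ensembl id and column 2 as symbol.
#' @param species `"human"` or `"mouse"`.
#'
#' @return An object of class `cc_counts`: list with `values` (genes x cells
#'   matrix), `gene_ids`, `cell_ids`, `id_type`, `species`.
#' @export
read_matrix <- function(path, format = c("mtx_dir", "csv", "tsv"),
                        id_type = c("symbol", "ensembl"),
                        species = c("human", "mouse")) {
  format <- match.arg(format)
  id_type <- match.arg(id_type)
  species <- match.arg(species)
  if (!file.exists(path)) {
    stop_ccann(sprintf("path does not exist: %s", path), class = "ccann_io_error")
  }
  if (format == "mtx_dir") {
    res <- read_mtx_dir(path, id_type)
  } else {
    res <- read_delim_matrix(path, if (format == "csv") "," else "\t")
  }
  values <- res$values
  gene_ids <- res$gene_ids
  if (anyDuplicated(gene_ids)) {
    n_dup <- sum(duplicated(gene_ids))
    rlang::warn(sprintf("%d duplicated gene id(s) summed", n_dup))
    values <- rowsum(values, group = gene_ids, reorder = FALSE)
    gene_ids <- rownames(values)
  }
  rownames(values) <- gene_ids
  colnames(values) <- res$cell_ids
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = res$cell_ids,
         id_type = id_type, species = species),
    class = "cc_counts"
  )
}

find_member <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      f <- file.path(dir, paste0(stem, ext))
      if (file.exists(f)) return(f)
    }
  }
  stop_ccann(sprintf("no %s[.gz] found in %s", stems[1], dir),
             class = "ccann_format_error")
}

read_mtx_dir <- function(dir, id_type) {
  mat_f <- find_member(dir, c("matrix.mtx"))
  feat_f <- find_member(dir, c("features.tsv", "genes.tsv"))
  bc_f <- find_member(dir, c("barcodes.tsv"))
  m <- as.matrix(Matrix::readMM(mat_f))
  feats <- utils::read.delim(feat_f, header = FALSE, stringsAsFactors = FALSE)
  bcs <- tryCatch(
    utils::read.delim(bc_f, header = FALSE, stringsAsFactors = FALSE)[[1]],
    error = function(e) character(0)
  )
  if (length(bcs) == 0) {
    stop_ccann("barcodes file is empty", class = "ccann_format_error")
  }
  if (nrow(feats) != nrow(m)) {
    stop_ccann(sprintf("features file has %d rows but matrix has %d",
                       nrow(feats), nrow(m)), class = "ccann_format_error")
  }
  if (length(bcs) != ncol(m)) {
    stop_ccann(sprintf("barcodes file has %d entries but matrix has %d columns",
                       length(bcs), ncol(m)), class = "ccann_format_error")
  }
  id_col <- if (ncol(feats) >= 2 && id_type == "symbol") 2L else 1L
  list(values = m, gene_ids = as.character(feats[[id_col]]), cell_ids = bcs)
}

read_delim_matrix <- function(path, delim) {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2) {
    stop_ccann("delimited matrix needs a gene-id column plus at least one cell",
               class = "ccann_format_error")
  }
  gene_ids <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  list(values = values, gene_ids = gene_ids, cell_ids = colnames(df)[-1])
}

#' Normalize a count matrix
#'
#' Two normalizations are offered. `log_cpm` is the standard library-size
#' log-normalization `log(1 + 10000 * count / cell_total)`. `pearson_residual`
#' computes analytic Pearson residuals under a negative-binomial
#' mean--sequencing-depth model: the expected count of gene i in cell j is
#' `mu_ij = depth_j * gene_total_i / grand_total`, the residual is
#' `(x - mu) / sqrt(mu + mu^2 / theta_i)` with a regularized per-gene
#' dispersion `theta_i` (see [gene_dispersion()]), clipped to
#' `+/- sqrt(n_cells)`. All-zero genes map to all-zero rows; both methods are
#' deterministic.
#'
#' @param counts A `cc_counts` object or a genes x cells nonnegative matrix.
#' @param method `"pearson_residual"` or `"log_cpm"`.
#' @return A genes x cells numeric matrix with the input dimnames and a
#'   `"normalization"` attribute recording the method.
#' @export
normalize_matrix <- function(counts, method = c("pearson_residual", "log_cpm")) {
  method <- match.arg(method)
  x <- as_gene_matrix(counts)
  if (any(x < 0)) stop_ccann("counts must be nonnegative")
  depth <- colSums(x)
  if (any(depth == 0)) {
    bad <- colnames(x)[depth == 0]
    stop_ccann(sprintf("cell(s) with zero total count: %s",
                       paste(head(bad, 5), collapse = ", ")),
               class = "ccann_format_error")
  }
  out <- if (method == "log_cpm") {
    log1p(sweep(x, 2, 10000 / depth, "*"))
  } else {
    pearson_residuals(x, depth)
  }
  dimnames(out) <- dimnames(x)
  attr(out, "normalization") <- method
  out
}

pearson_residuals <- function(x, depth) {
  gene_tot <- rowSums(x)
  p <- gene_tot / sum(x)
  mu <- outer(p, depth)                       # genes x cells expected counts
  theta <- gene_dispersion(x, mu)
  denom <- sqrt(mu + mu^2 / theta)
  r <- (x - mu) / denom
  r[gene_tot == 0, ] <- 0                     # all-zero genes: 0/0 -> 0
  clip <- sqrt(ncol(x))
  pmin(pmax(r, -clip), clip)
}

#' Regularized per-gene negative-binomial dispersion
#'
#' Method-of-moments estimate of the NB size parameter theta for each gene
#' under the depth model used by [normalize_matrix()]:
#' `theta_i = sum(mu_ij^2) / sum((x_ij - mu_ij)^2 - mu_ij)`. Genes whose
#' counts are at or below Poisson variance get `theta = Inf`. Estimates are
#' regularized by a loess fit of `log10(theta)` against `log10(mean count)`
#' (median fallback when fewer than 20 finite estimates are available), which
#' stabilizes the per-gene noise in theta.
#'
#' @param x Genes x cells count matrix.
#' @param mu Matrix of expected counts (same shape); computed from `x` when
#'   omitted.
#' @return Per-gene theta vector (possibly `Inf`).
#' @export
gene_dispersion <- function(x, mu = NULL) {
  x <- as_gene_matrix(x)
  if (is.null(mu)) {
    depth <- colSums(x)
    mu <- outer(rowSums(x) / sum(x), depth)
  }
  excess <- rowSums((x - mu)^2 - mu)
  theta_raw <- ifelse(excess > 0, rowSums(mu^2) / excess, Inf)
  gm <- rowMeans(x)
  ok <- is.finite(theta_raw) & gm > 0 & theta_raw > 0
  if (sum(ok) >= 20 && length(unique(gm[ok])) >= 10) {
    df <- data.frame(lx = log10(gm[ok]), ly = log10(theta_raw[ok]))
    fit <- stats::loess(ly ~ lx, data = df, span = 1, degree = 1,
                        family = "symmetric")
    pred <- rep(NA_real_, length(theta_raw))
    gm_pos <- gm > 0
    pred[gm_pos] <- stats::predict(fit, newdata = data.frame(lx = log10(gm[gm_pos])))
    # loess extrapolation outside the fitted range returns NA: keep raw there
    theta <- ifelse(is.na(pred), theta_raw, 10^pred)
  } else {
    med <- if (any(ok)) median(theta_raw[ok]) else Inf
    theta <- rep(med, length(theta_raw))
  }
  theta[gm == 0] <- Inf
  pmax(theta, 1e-4)
}

#' Define the classifier's feature space
#'
#' The feature space fixes the ordered list of classifier input genes, the
#' ordered class vocabulary, optional per-state marker sets (used by the
#' regression module), and bundled identifier translation tables.
#'
#' @param feature_ids Ordered, unique classifier input genes.
#' @param state_names Ordered class vocabulary.
#' @param marker_sets Optional named list (state -> marker gene character
#'   vector); every marker gene must be a feature or resolvable via
#'   `id_maps`.
#' @param id_maps Optional list of translation tables: `ensembl_symbol`, a
#'   data frame with columns `ensembl` and `symbol`; `mouse_human`, a data
#'   frame with columns `mouse` and `human` (one-to-one orthologs).
#' @param id_type Identifier system of `feature_ids`.
#' @return An object of class `cc_feature_space`.
#' @export
feature_space <- function(feature_ids, state_names = CC_STATES,
                          marker_sets = NULL, id_maps = list(),
                          id_type = c("symbol", "ensembl")) {
  id_type <- match.arg(id_type)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(feature_ids)) {
    stop_ccann("`feature_ids` must be unique", class = "ccann_invalid_parameter")
  }
  if (anyDuplicated(state_names)) {
    stop_ccann("`state_names` must be unique", class = "ccann_invalid_parameter")
  }
  if (!is.null(marker_sets)) {
    known <- unique(c(feature_ids,
                      unlist(lapply(id_maps, function(m) unlist(m)))))
    missing <- setdiff(unlist(marker_sets), known)
    if (length(missing)) {
      stop_ccann(sprintf("marker genes not resolvable in the feature space: %s",
                         paste(head(missing, 5), collapse = ", ")),
                 class = "ccann_invalid_parameter")
    }
  }
  structure(
    list(feature_ids = feature_ids, state_names = as.character(state_names),
         marker_sets = marker_sets, id_maps = id_maps, id_type = id_type),
    class = "cc_feature_space"
  )
}

#' Build a feature space from a marker table
#'
#' Mirrors the training recipe in which the classifier's input genes are the
#' genes up-regulated in at least one state: features are the unique genes of
#' the marker table (in first-appearance order) and `marker_sets` groups them
#' by state.
#'
#' @param markers A marker tibble from [find_state_markers()].
#' @inheritParams feature_space
#' @return A `cc_feature_space`.
#' @export
feature_space_from_markers <- function(markers, state_names = CC_STATES,
                                       id_maps = list(),
                                       id_type = c("symbol", "ensembl")) {
  stopifnot(is.data.frame(markers), all(c("gene", "state") %in% names(markers)))
  feature_space(
    feature_ids = unique(markers$gene),
    state_names = state_names,
    marker_sets = split(markers$gene, markers$state)[
      intersect(state_names, unique(markers$state))],
    id_maps = id_maps,
    id_type = match.arg(id_type)
  )
}

#' Align a normalized matrix to the classifier's feature space
#'
#' Translates gene identifiers into the feature space's identifier system
#' (mouse genes through the bundled one-to-one ortholog table; symbol/Ensembl
#' through the bundled lookup), reorders genes to `feature_ids`, zero-fills
#' classifier genes absent from the input, and reports the missing fraction.
#' A warning is emitted when more than `missing_warn_fraction` of classifier
#' genes are missing, since classification error grows quickly with missing
#' input genes; full non-overlap is an error.
#'
#' @param expr Normalized genes x cells matrix (rownames = gene ids), a
#'   `cc_counts` object, or an already-aligned `cc_aligned` (returned
#'   unchanged when its feature space matches).
#' @param space A [feature_space()].
#' @param id_type,species Identifier system and species of the input rows
#'   (defaults taken from `expr` when it is a `cc_counts`).
#' @param missing_warn_fraction Warn when `missing_fraction` exceeds this.
#' @return An object of class `cc_aligned`: list with `values` (cells x
#'   features matrix, columns exactly `space$feature_ids`),
#'   `missing_fraction`, and `provenance` (normalization tag).
#' @export
align_features <- function(expr, space,
                           id_type = c("symbol", "ensembl"),
                           species = c("human", "mouse"),
                           missing_warn_fraction = 0.2) {
  stopifnot(inherits(space, "cc_feature_space"))
  if (inherits(expr, "cc_aligned")) {
    if (!identical(colnames(expr$values), space$feature_ids)) {
      stop_ccann("input is aligned to a different feature space",
                 class = "ccann_invalid_parameter")
    }
    return(expr)
  }
  if (inherits(expr, "cc_counts")) {
    id_type <- expr$id_type
    species <- expr$species
    expr <- expr$values
  } else {
    id_type <- match.arg(id_type)
    species <- match.arg(species)
  }
  x <- as_gene_matrix(expr)
  prov <- attr(expr, "normalization") %||% "unknown"
  ids <- rownames(x)
  if (is.null(ids)) stop_ccann("expression matrix must have gene rownames")

  if (species == "mouse") {
    map <- space$id_maps$mouse_human
    if (is.null(map)) {
      stop_ccann("feature space has no mouse_human ortholog table",
                 class = "ccann_invalid_parameter")
    }
    ids <- translate_ids(ids, map, "mouse", "human", what = "ortholog")
  }
  if (id_type != space$id_type) {
    map <- space$id_maps$ensembl_symbol
    if (is.null(map)) {
      stop_ccann("feature space has no ensembl_symbol lookup table",
                 class = "ccann_invalid_parameter")
    }
    ids <- translate_ids(ids, map, id_type, space$id_type, what = "identifier")
  }

  keep <- !is.na(ids) & !duplicated(ids)
  if (sum(keep) < length(ids)) {
    rlang::inform(sprintf("%d gene(s) dropped during identifier translation",
                          length(ids) - sum(keep)))
  }
  x <- x[keep, , drop = FALSE]
  rownames(x) <- ids[keep]

  idx <- match(space$feature_ids, rownames(x))
  aligned <- matrix(0, nrow = ncol(x), ncol = length(space$feature_ids),
                    dimnames = list(colnames(x), space$feature_ids))
  present <- !is.na(idx)
  aligned[, present] <- t(x[idx[present], , drop = FALSE])
  missing_fraction <- mean(!present)
  if (missing_fraction == 1) {
    stop_ccann("no overlap between input genes and the classifier feature space",
               class = "ccann_format_error")
  }
  if (missing_fraction > missing_warn_fraction) {
    rlang::warn(sprintf(
      "%.1f%% of classifier genes are missing from the input (zero-filled); classification error rises steeply beyond %.0f%% missing",
      100 * missing_fraction, 100 * missing_warn_fraction))
  }
  structure(
    list(values = aligned, missing_fraction = missing_fraction,
         provenance = prov),
    class = "cc_aligned"
  )
}

# One-to-one translation: ambiguous source or target ids are dropped (NA),
# never guessed. `map` has columns named by `from` and `to`.
translate_ids <- function(ids, map, from, to, what = "identifier") {
  stopifnot(all(c(from, to) %in% names(map)))
  src <- as.character(map[[from]])
  dst <- as.character(map[[to]])
  ambiguous <- src %in% src[duplicated(src)] | dst %in% dst[duplicated(dst)]
  src <- src[!ambiguous]
  dst <- dst[!ambiguous]
  out <- dst[match(ids, src)]
  n_drop <- sum(is.na(out) & !is.na(ids))
  if (n_drop > 0) {
    rlang::inform(sprintf("%d gene(s) without a unique %s mapping", n_drop, what))
  }
  out
}

#' @export
print.cc_aligned <- function(x, ...) {
  cat(sprintf("<cc_aligned> %d cells x %d features (%.1f%% missing, %s-normalized)\n",
              nrow(x$values), ncol(x$values), 100 * x$missing_fraction,
              x$provenance))
  invisible(x)
}
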