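test_that("planted markers are recovered and constants are excluded", {
  p <- synthetic_params(n_genes = 300, seed = 77)
  d <- simulate_dataset(p, 2000)
  norm <- normalize_matrix(d$counts, "log_cpm")
  norm <- rbind(norm, constant_gene = rep(2, ncol(norm)))
  mk <- find_state_markers(norm, d$labels)
  for (s in names(d$marker_sets)) {
    recovery <- mean(d$marker_sets[[s]] %in% mk$gene[mk$state == s])
    expect_gte(recovery, 0.9)
  }
  expect_false("constant_gene" %in% mk$gene)
  expect_true(all(mk$p_adj >= mk$p))
  expect_true(all(mk$log2fc >= 0.25))
  # impossible fold-change cutoff empties the table
  empty <- find_state_markers(norm, d$labels, logfc_min = Inf)
  expect_identical(nrow(empty), 0L)
})

test_that("marker tables shrink monotonically as cutoffs tighten", {
  p <- synthetic_params(n_genes = 200, seed = 31)
  d <- simulate_dataset(p, 600)
  norm <- normalize_matrix(d$counts, "log_cpm")
  loose <- find_state_markers(norm, d$labels, logfc_min = 0.1, padj_max = 0.2)
  tight_fc <- find_state_markers(norm, d$labels, logfc_min = 0.5, padj_max = 0.2)
  tight_p <- find_state_markers(norm, d$labels, logfc_min = 0.1, padj_max = 0.01)
  key <- function(m) paste(m$gene, m$state)
  expect_true(all(key(tight_fc) %in% key(loose)))
  expect_true(all(key(tight_p) %in% key(loose)))
})

test_that("the rank-sum p-values match wilcox.test gene by gene", {
  withr::with_seed(13, {
    x <- matrix(rnbinom(60 * 40, size = 2, mu = 6), nrow = 60,
                dimnames = list(paste0("g", 1:60), paste0("c", 1:40)))
    labels <- sample(c("A", "B", "C"), 40, replace = TRUE)
  })
  norm <- normalize_matrix(x, "log_cpm")
  mk <- find_state_markers(norm, labels, logfc_min = -Inf, padj_max = 1)
  for (g in paste0("g", c(1, 7, 33))) {
    for (s in c("A", "B")) {
      ref <- wilcox.test(norm[g, labels == s], norm[g, labels != s],
                         exact = FALSE, correct = TRUE)$p.value
      got <- mk$p[mk$gene == g & mk$state == s]
      expect_equal(got, ref, tolerance = 1e-10)
    }
  }
})

test_that("states with fewer than 3 cells are rejected by name", {
  x <- matrix(1:40, nrow = 4, dimnames = list(paste0("g", 1:4), NULL))
  labels <- c(rep("A", 8), rep("Tiny", 2))
  expect_error(find_state_markers(x, labels, delog = FALSE), "Tiny")
  expect_error(find_state_markers(x, rep("A", 10), delog = FALSE),
               "at least 2 states")
})

test_that("hypergeometric overlap handles degenerate sets", {
  u <- paste0("g", 1:20)
  disjoint <- hypergeom_overlap(u[1:5], u[6:10], u)
  expect_identical(disjoint$n_overlap, 0L)
  expect_equal(disjoint$p_value, 1, tolerance = 1e-12)
  full <- hypergeom_overlap(u, u, u)
  expect_equal(full$p_value, 1, tolerance = 1e-12)
  expect_error(hypergeom_overlap(c(u[1], "alien"), u[1:3], u), "alien")
})

test_that("hypergeometric p-values match exhaustive subset enumeration", {
  # brute force: enumerate every possible draw of |b| genes from the universe
  brute_p <- function(size_a, size_b, n_overlap, universe) {
    draws <- utils::combn(length(universe), size_b)
    in_a <- seq_len(size_a)
    hits <- apply(draws, 2, function(cols) sum(cols %in% in_a) >= n_overlap)
    mean(hits)
  }
  cases <- list(c(12, 5, 5, 3), c(12, 4, 6, 2), c(10, 3, 3, 1), c(8, 4, 4, 4),
                c(20, 5, 5, 3))
  for (cs in cases) {
    u <- paste0("g", seq_len(cs[1]))
    a <- u[seq_len(cs[2])]
    b <- c(u[seq_len(cs[4])], rev(u)[seq_len(cs[3] - cs[4])])
    got <- hypergeom_overlap(a, b, u)
    expect_identical(got$n_overlap, as.integer(cs[4]))
    expect_equal(got$p_value, brute_p(cs[2], cs[3], cs[4], u),
                 tolerance = 1e-12)
  }
})

test_that("cell-to-bulk Spearman correlations match the rank formula", {
  genes <- paste0("g", 1:5)
  bulk <- matrix(c(50, 40, 30, 20, 11), ncol = 1,
                 dimnames = list(genes, "rep1"))
  cells <- cbind(same = c(5, 4, 3, 2, 1),
                 anti = c(1, 2, 3, 4, 5),
                 mixed = c(3, 5, 1, 4, 2))
  rownames(cells) <- genes
  cor_tab <- correlate_signature(cells, bulk, n_hvg = 5, bulk_min = 10,
                                 min_shared = 5)
  rho <- function(cell) cor_tab$rho[cor_tab$cell_id == cell]
  expect_equal(rho("same"), 1)
  expect_equal(rho("anti"), -1)
  # untied ranks: 1 - 6*sum(d^2) / (n(n^2-1))
  d2 <- sum((rank(cells[, "mixed"]) - rank(bulk[, 1]))^2)
  expect_equal(rho("mixed"), 1 - 6 * d2 / (5 * 24))
})

test_that("Spearman correlation is invariant to monotone transforms", {
  withr::with_seed(3, {
    genes <- paste0("g", 1:30)
    cells <- matrix(rexp(30 * 4), nrow = 30, dimnames = list(genes, paste0("c", 1:4)))
    bulk <- matrix(rexp(30) * 50 + 11, ncol = 1, dimnames = list(genes, "rep1"))
  })
  base <- correlate_signature(cells, bulk, n_hvg = 30, bulk_min = 0,
                              min_shared = 10)
  warped <- correlate_signature(cells^3, bulk, n_hvg = 30, bulk_min = 0,
                                min_shared = 10)
  expect_equal(base$rho, warped$rho, tolerance = 1e-12)
  expect_error(correlate_signature(cells[1:4, ], bulk[1:4, , drop = FALSE],
                                   min_shared = 10),
               "usable shared gene")
})

test_that("signature-positive calls require the cutoff in every replicate", {
  tab <- tibble::tibble(
    cell_id = rep(c("both", "one", "neither", "edge"), each = 2),
    replicate = rep(c("rep1", "rep2"), 4),
    rho = c(0.15, 0.12, 0.15, 0.05, -0.2, 0.02, 0.1, 0.1))
  calls <- call_signature_positive(tab, cutoff = 0.1)
  got <- setNames(calls$positive, calls$cell_id)
  expect_true(got[["both"]])
  expect_false(got[["one"]])
  expect_false(got[["neither"]])
  expect_true(got[["edge"]])                 # >= is inclusive
  all_pos <- call_signature_positive(tab, cutoff = -1)
  expect_true(all(all_pos$positive))
})

test_that("planted bulk signatures light up their own state's cells", {
  fx <- small_pipeline()
  d <- fx$dataset
  sig <- simulate_bulk_signature(d, "Neural G0", n_replicates = 2)
  cor_tab <- correlate_signature(
    fx$lognorm, sig, extra_genes = fx$space$feature_ids)
  calls <- call_signature_positive(cor_tab, cutoff = 0.1)
  pos_rate <- tapply(calls$positive[match(colnames(d$counts), calls$cell_id)],
                     d$labels, mean)
  expect_identical(names(which.max(pos_rate)), "Neural G0")
})
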