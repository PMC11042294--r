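# Internal helpers shared across modules.

stop_ccann <- function(msg, class = "ccann_error") {
  rlang::abort(msg, class = c(class, "ccann_error"))
}

# Derive a reproducible child seed from a parent seed and a stream label.
# Keeps derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

# Coerce the expression slot of the various containers to a base dense matrix
# (genes x cells). Accepts cc_counts, Matrix classes and plain matrices.
as_gene_matrix <- function(x) {
  if (inherits(x, "cc_counts")) x <- x$values
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x)) stop_ccann("expected a genes x cells matrix")
  x
}

check_prob <- function(x, name, closed_top = TRUE) {
  hi_ok <- if (closed_top) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || !hi_ok) {
    stop_ccann(sprintf("`%s` must be a probability in [0, %s)", name,
                       if (closed_top) "1]" else "1"),
               class = "ccann_invalid_parameter")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop_ccann(sprintf("`%s` must be an integer >= %d", name, min),
               class = "ccann_invalid_parameter")
  }
  invisible(as.integer(x))
}
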