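# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package go
# through this so that a seed argument fully determines the result.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed, kept inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop(sprintf("'%s' must be a numeric matrix (genes x samples)", what))
  if (any(counts < 0)) stop(sprintf("'%s' contains negative entries", what))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(sprintf("'%s' must have gene rownames and sample colnames", what))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  invisible(counts)
}

# Mann-Whitney AUC with midrank tie handling: probability that a value from
# the positive group exceeds one from the negative group, ties counting 1/2.
# Shared by gene_auc() and roc_auc().
auc_ustat <- function(pos, neg) {
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) stop("both groups must be non-empty")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

geometric_mean_rows <- function(m) exp(rowMeans(log(m)))

row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}
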