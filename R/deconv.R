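#' Cell-type-of-origin deconvolution by non-negative least squares
#'
#' Each sample's counts are reduced to relative abundances over the genes
#' shared with the reference; the reference profiles are row-renormalized
#' over the same genes; fractions solve `min || x - t(R) theta ||^2` subject
#' to `theta >= 0` and are then renormalized to sum to 1. The solver is
#' deterministic (active-set NNLS), so fractions are invariant to rescaling
#' a sample's counts.
#'
#' @param counts Gene x sample count matrix.
#' @param reference A `cfrna_reference` (or list with `profiles` cell types x
#'   genes and `cell_type_ids`).
#' @return A `cfrna_fractions` matrix (samples x cell types), rows summing
#'   to 1.
#' @export
deconvolve <- function(counts, reference) {
  assert_count_matrix(counts)
  profiles <- reference$profiles
  shared <- intersect(rownames(counts), colnames(profiles))
  if (length(shared) < nrow(profiles))
    stop("need at least as many shared genes as cell types")
  R <- profiles[, shared, drop = FALSE]
  R <- R / rowSums(R)
  A <- t(R)  # genes x cell types
  if (qr(A)$rank < nrow(profiles))
    stop("reference is rank-deficient on the shared genes; ",
         "fractions are non-identifiable")
  theta <- matrix(0, ncol(counts), nrow(profiles),
                  dimnames = list(colnames(counts), rownames(profiles)))
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[shared, j])
    if (tot == 0) stop("sample ", colnames(counts)[j],
                       " has zero counts on shared genes")
    x <- counts[shared, j] / tot
    sol <- pracma::lsqnonneg(A, x)$x
    if (sum(sol) <= 0) stop("degenerate NNLS solution for sample ",
                            colnames(counts)[j])
    theta[j, ] <- sol / sum(sol)
  }
  class(theta) <- c("cfrna_fractions", class(theta))
  theta
}

#' Min-max scale fractions per cell type across a cohort
#'
#' Column-wise `(v - min)/(max - min)` so every cell type spans 0 to 1
#' across the cohort (medians of these scaled values are what group
#' comparisons plot). Constant columns are set to zero and flagged in the
#' `"constant_columns"` attribute.
#'
#' @param fractions Samples x cell types matrix.
#' @return Scaled matrix with the same dimnames.
#' @export
scale_fractions <- function(fractions) {
  if (is.null(dim(fractions)) || nrow(fractions) == 0)
    stop("fractions must be a non-empty matrix")
  rng <- apply(fractions, 2, range)
  span <- rng[2, ] - rng[1, ]
  constant <- span == 0
  span[constant] <- 1
  out <- sweep(sweep(fractions, 2, rng[1, ], "-"), 2, span, "/")
  out[, constant] <- 0
  attr(out, "constant_columns") <- colnames(fractions)[constant]
  out
}

# Two-sided Wilcoxon rank-sum test. Exact enumeration of the rank-sum null
# (valid with ties) when both groups have <= `exact_max` samples; otherwise
# the normal approximation with tie correction and continuity correction.
wilcoxon_rank_sum <- function(a, b, exact_max = 10) {
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0 || n_b == 0) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  if (n_a <= exact_max && n_b <= exact_max) {
    combos <- utils::combn(n_a + n_b, n_a)
    sums <- colSums(matrix(r[combos], nrow = n_a))
    sums <- round(sums, 8)
    w_r <- round(w, 8)
    p <- min(1, 2 * min(mean(sums <= w_r), mean(sums >= w_r)))
    return(list(statistic = w - n_a * (n_a + 1) / 2, p_value = p,
                exact = TRUE))
  }
  n <- n_a + n_b
  mu <- n_a * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  list(statistic = w - n_a * (n_a + 1) / 2,
       p_value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Compare scaled cell-type fractions between two groups
#'
#' Per cell type, a two-sided Wilcoxon rank-sum test on the (scaled)
#' fractions between the two groups, BH-adjusted across cell types (one
#' family per contrast), with group medians of the scaled fractions.
#' Samples with `NA` group are excluded — the ALT contrast built by
#' [stratify_alt()] uses this to drop intermediate ALT values.
#'
#' @param fractions Samples x cell types matrix ([deconvolve()] output,
#'   typically after [scale_fractions()]).
#' @param groups Factor/character per sample with exactly two non-NA levels.
#' @return data.frame: cell_type, median per group, W statistic, p_value,
#'   q_value.
#' @export
compare_groups <- function(fractions, groups) {
  groups <- as.character(groups)
  keep <- !is.na(groups)
  fractions <- fractions[keep, , drop = FALSE]
  groups <- groups[keep]
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups required after ",
                             "stratification (got ", length(lev), ")")
  if (min(table(groups)) == 0) stop("a group is empty after stratification")
  res <- lapply(colnames(fractions), function(ct) {
    a <- fractions[groups == lev[1], ct]
    b <- fractions[groups == lev[2], ct]
    t <- wilcoxon_rank_sum(a, b)
    data.frame(cell_type = ct,
               median_1 = stats::median(a), median_2 = stats::median(b),
               statistic = t$statistic, p_value = t$p_value)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("median_", lev)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Stratify samples by ALT for the liver contrast
#'
#' Normal: ALT < 40 IU/L; high: ALT > 100 IU/L; samples with
#' 40 <= ALT <= 100 are excluded (NA).
#'
#' @param alt Numeric ALT measurements (IU/L).
#' @return Character vector "normal"/"high"/NA.
#' @export
stratify_alt <- function(alt) {
  ifelse(alt < 40, "normal", ifelse(alt > 100, "high", NA_character_))
}
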