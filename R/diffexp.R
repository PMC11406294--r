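#' Per-gene negative-binomial Wald test between two groups
#'
#' Fits, per gene, the NB log-link model `mean_ij = s_j * exp(b0 + b1 * x_j)`
#' (x_j = 1 for group B) by iteratively reweighted least squares with fixed
#' per-gene dispersion, and reports the Wald test of b1 = 0. Dispersions are
#' trend-moderated when a trend is supplied: `phi_i = max(phi_i, a0 + a1/mu_i)`
#' with mu_i the mean normalized count. Genes with all-zero counts, or whose
#' fit does not converge (e.g., complete separation), are reported with NA
#' statistics and excluded from the BH family.
#'
#' @param counts Gene x sample count matrix (both groups).
#' @param s Named size factors for the samples in `counts`.
#' @param dispersions Named per-gene NB dispersions (variance = mu + phi mu^2).
#' @param labels Factor/character vector per sample with exactly two levels.
#' @param group_a,group_b The reference and comparison group labels; log2
#'   fold changes are group B vs group A.
#' @param trend Optional c(a0, a1) dispersion trend for moderation.
#' @param max_iter,tol IRLS controls.
#' @return data.frame: `gene`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `p_value`, `q_value` (BH over the tested genes).
#' @export
nb_wald_test <- function(counts, s, dispersions, labels,
                         group_a = NULL, group_b = NULL, trend = NULL,
                         max_iter = 50L, tol = 1e-8) {
  assert_count_matrix(counts)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (is.null(group_a)) group_a <- sort(lev)[1]
  if (is.null(group_b)) group_b <- setdiff(sort(lev), group_a)[1]
  in_a <- labels == group_a
  in_b <- labels == group_b
  if (!any(in_a) || !any(in_b))
    stop("both groups must be non-empty (got ", sum(in_a), " vs ", sum(in_b), ")")
  keep <- in_a | in_b
  K <- counts[, keep, drop = FALSE]
  s <- s[colnames(K)]
  x <- as.numeric(in_b[keep])

  q <- sweep(K, 2, s, "/")
  base_mean <- rowMeans(q)
  phi <- dispersions[rownames(K)]
  phi[is.na(phi)] <- 0
  if (!is.null(trend))
    phi <- pmax(phi, trend[1] + trend[2] / pmax(base_mean, 1e-8))

  G <- nrow(K); n <- ncol(K)
  A <- x == 0
  eps <- 1e-8
  mA <- rowMeans(q[, A, drop = FALSE]); mB <- rowMeans(q[, !A, drop = FALSE])
  b0 <- log(pmax(mA, 1e-3))
  b1 <- log(pmax(mB, 1e-3)) - b0
  testable <- rowSums(K) > 0
  converged <- rep(FALSE, G)

  sx <- matrix(s, G, n, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(b0 + outer(b1, x), -50), 50)  # G x n linear predictor
    mu <- sx * exp(eta)
    w <- mu / (1 + phi * mu)
    w <- pmax(w, 1e-10)
    z <- eta + (K - mu) / mu
    SwA <- rowSums(w[, A, drop = FALSE])
    SwB <- rowSums(w[, !A, drop = FALSE])
    b0_new <- rowSums((w * z)[, A, drop = FALSE]) / SwA
    bB <- rowSums((w * z)[, !A, drop = FALSE]) / SwB
    b1_new <- bB - b0_new
    b0_new <- pmin(pmax(b0_new, -50), 50)
    b1_new <- pmin(pmax(b1_new, -50), 50)
    delta <- pmax(abs(b0_new - b0), abs(b1_new - b1))
    newly <- !converged & delta < tol & testable
    converged <- converged | newly
    b0 <- b0_new; b1 <- b1_new
    if (all(converged | !testable)) break
  }

  eta <- pmin(pmax(b0 + outer(b1, x), -50), 50)
  mu <- sx * exp(eta)
  w <- pmax(mu / (1 + phi * mu), 1e-10)
  SwA <- rowSums(w[, A, drop = FALSE])
  SwB <- rowSums(w[, !A, drop = FALSE])
  se <- sqrt(1 / SwA + 1 / SwB)

  ok <- testable & converged & abs(b1) < 49.9
  log2fc <- ifelse(ok, b1 / log(2), NA_real_)
  se_out <- ifelse(ok, se / log(2), NA_real_)
  stat <- ifelse(ok, b1 / se, NA_real_)
  p <- ifelse(ok, 2 * stats::pnorm(-abs(stat)), NA_real_)

  data.frame(gene = rownames(K), base_mean = base_mean, log2fc = log2fc,
             se = se_out, stat = stat, p_value = p,
             q_value = bh_adjust(p), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: in ascending order of p, `q_(k) = min_{j >= k}
#' m p_(j) / j` capped at 1, original order restored. NAs are preserved and
#' excluded from the family size m.
#'
#' @param p Numeric vector of p-values in [0, 1]; NAs allowed.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene ROC-AUC on transformed abundances
#'
#' For each gene, the probability that a group-B value exceeds a group-A
#' value (ties counting one half) — the Mann-Whitney U statistic scaled by
#' `n_A * n_B`, equivalently the trapezoidal ROC area.
#'
#' @param vst_matrix Gene x sample matrix of VST values.
#' @param labels Two-group factor/character vector per sample.
#' @param group_a,group_b Orientation; AUC > 0.5 means elevated in group B.
#' @return Named numeric vector of per-gene AUCs in [0, 1].
#' @export
gene_auc <- function(vst_matrix, labels, group_a = NULL, group_b = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (is.null(group_a)) group_a <- lev[1]
  if (is.null(group_b)) group_b <- setdiff(lev, group_a)[1]
  in_a <- labels == group_a; in_b <- labels == group_b
  if (!any(in_a) || !any(in_b)) stop("both groups must be non-empty")
  n_a <- sum(in_a); n_b <- sum(in_b)
  sub <- vst_matrix[, in_a | in_b, drop = FALSE]
  pos <- labels[in_a | in_b] == group_b
  auc <- apply(sub, 1, function(v) {
    r <- rank(v)
    (sum(r[pos]) - n_b * (n_b + 1) / 2) / (n_a * n_b)
  })
  stats::setNames(auc, rownames(vst_matrix))
}

#' Exclusive intersection counts over named gene sets
#'
#' For k named sets, counts genes belonging to exactly each of the 2^k - 1
#' non-empty membership patterns (UpSet semantics); pattern counts sum to the
#' size of the union.
#'
#' @param sets Named list of character vectors (>= 2 sets, unique names).
#' @return data.frame with one logical membership column per set, a
#'   `pattern` label (ampersand-joined set names) and `count`.
#' @export
intersect_dag_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least two named sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(names(sets) == ""))
    stop("sets must have unique non-empty names")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  k <- length(sets)
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))[-1, , drop = FALSE]
  colnames(patterns) <- names(sets)
  counts <- apply(patterns, 1, function(pat) {
    sum(apply(member, 1, function(row) all(row == pat)))
  })
  out <- as.data.frame(patterns)
  out$pattern <- apply(patterns, 1, function(pat)
    paste(names(sets)[pat], collapse = "&"))
  out$count <- as.integer(counts)
  rownames(out) <- NULL
  out
}

#' Two-group differential abundance with gene AUC
#'
#' Convenience wrapper running [nb_wald_test()] with the model's trend-
#' moderated dispersions and attaching per-gene AUC computed on VST values.
#'
#' @param counts Gene x sample counts for the samples being compared.
#' @param model A `cfrna_norm` fitted on (a superset of) these samples; new
#'   samples are projected through it for size factors.
#' @param labels Group label per column of `counts`.
#' @param group_a,group_b Comparison orientation (B vs A).
#' @return DEResult data.frame with `gene_auc` column appended.
#' @export
run_de <- function(counts, model, labels, group_a, group_b) {
  proj <- project_new_samples(model, counts)
  res <- nb_wald_test(counts, proj$size_factors, model$dispersions, labels,
                      group_a = group_a, group_b = group_b,
                      trend = model$trend)
  auc <- gene_auc(proj$vst, labels, group_a = group_a, group_b = group_b)
  res$gene_auc <- auc[res$gene]
  res
}
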