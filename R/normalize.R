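#' Median-of-ratios size factors
#'
#' For each sample j, `s_j = median_i K_ij / g_i` over "usable" genes (no
#' zero count in any sample), where `g_i` is the geometric mean of gene i
#' across samples.
#'
#' @param counts Gene x sample count matrix with dimnames.
#' @return Named numeric vector of size factors.
#' @export
estimate_size_factors <- function(counts) {
  assert_count_matrix(counts)
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable))
    stop("no usable genes: every gene has a zero count in some sample; ",
         "a pseudo-reference fallback is not silently applied")
  g <- geometric_mean_rows(counts[usable, , drop = FALSE])
  s <- apply(counts[usable, , drop = FALSE] / g, 2, stats::median)
  stats::setNames(s, colnames(counts))
}

#' Gene-wise dispersion estimates with a parametric trend
#'
#' Method-of-moments dispersions on size-factor-normalized counts,
#' `phi_i = max(0, (v_i - mu_i) / mu_i^2)`, followed by an iteratively
#' reweighted least-squares fit of the trend `phi(mu) = a0 + a1/mu` over
#' genes with positive dispersion, with outlier down-weighting (genes whose
#' dispersion deviates from the fitted trend by more than 10x are dropped
#' between iterations). Coefficients are clamped at zero.
#'
#' @param counts Gene x sample count matrix.
#' @param s Size factors from [estimate_size_factors()].
#' @return List with `dispersions` (named, per gene), `trend` = c(a0, a1),
#'   and `gene_means` (mean normalized counts).
#' @export
fit_dispersion <- function(counts, s) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples to estimate dispersion")
  q <- sweep(counts, 2, s, "/")
  mu <- rowMeans(q)
  v <- row_vars(q)
  phi <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  names(phi) <- rownames(counts)

  use <- which(phi > 0 & mu > 0)
  if (length(use) < 10)
    stop("fewer than 10 genes with positive dispersion: trend unidentifiable")
  a <- fit_dispersion_trend(phi[use], mu[use])
  list(dispersions = phi, trend = a, gene_means = stats::setNames(mu, rownames(counts)))
}

# IRLS fit of phi ~ a0 + a1/mu with gamma-like weights (1/fitted^2) and
# 10-fold outlier exclusion, as used for parametric dispersion trends.
fit_dispersion_trend <- function(phi, mu, max_iter = 10) {
  x <- 1 / mu
  keep <- rep(TRUE, length(phi))
  a <- c(stats::median(phi), 0)
  for (it in seq_len(max_iter)) {
    fitted <- pmax(a[1] + a[2] * x, 1e-8)
    w <- 1 / fitted^2
    fit <- stats::lm.wfit(cbind(1, x[keep]), phi[keep], w[keep])
    a_new <- pmax(fit$coefficients, 0)
    a_new[is.na(a_new)] <- 0
    fitted_new <- pmax(a_new[1] + a_new[2] * x, 1e-8)
    keep_new <- abs(log(phi / fitted_new)) < log(10)
    if (sum(keep_new) < 10) keep_new <- keep
    converged <- max(abs(a_new - a)) < 1e-8
    a <- a_new
    keep <- keep_new
    if (converged) break
  }
  stats::setNames(as.numeric(a), c("a0", "a1"))
}

#' Fit a normalization model on training samples
#'
#' Computes median-of-ratios size factors, a per-gene pseudo-reference
#' (geometric means; genes with any zero flagged unusable), gene-wise
#' dispersions and the parametric dispersion trend. The returned model is the
#' only object needed to variance-stabilize training data and to project new
#' samples without refitting (strict train/test separation).
#'
#' @param counts Training gene x sample count matrix.
#' @return A `cfrna_norm` object.
#' @export
fit_normalization <- function(counts) {
  assert_count_matrix(counts)
  s <- estimate_size_factors(counts)
  disp <- fit_dispersion(counts, s)
  usable <- rowSums(counts > 0) == ncol(counts)
  pseudo <- rep(NA_real_, nrow(counts))
  pseudo[usable] <- geometric_mean_rows(counts[usable, , drop = FALSE])
  names(pseudo) <- rownames(counts)
  structure(list(size_factors = s, pseudo_reference = pseudo,
                 dispersions = disp$dispersions, trend = disp$trend,
                 gene_means = disp$gene_means,
                 gene_ids = rownames(counts), version = "1"),
            class = "cfrna_norm")
}

#' @export
print.cfrna_norm <- function(x, ...) {
  cat("cfRNA normalization model:", length(x$gene_ids), "genes,",
      length(x$size_factors), "training samples\n")
  cat(sprintf("  dispersion trend: phi(mu) = %.4g + %.4g/mu\n",
              x$trend["a0"], x$trend["a1"]))
  cat(sprintf("  usable pseudo-reference genes: %d\n",
              sum(!is.na(x$pseudo_reference))))
  invisible(x)
}

# Closed-form NB variance stabilizer for v(mu) = mu*(1+a1) + a0*mu^2:
#   h(q) = log2( (1 + a1 + 2 a0 q + 2 sqrt(a0 q (1 + a1 + a0 q))) / (4 a0) )
# For a0 ~ 0 the variance is Poisson-like scaled by (1+a1) and the
# stabilizer falls back to 2*sqrt(q/(1+a1)).
vst_transform_q <- function(q, a0, a1) {
  if (any(q < 0)) stop("negative normalized counts passed to VST")
  if (a0 < 1e-12) return(2 * sqrt(q / (1 + a1)))
  log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
}

#' Variance-stabilizing transform of counts under a fitted model
#'
#' Normalized counts `q_ij = K_ij / s_j` are mapped through the closed-form
#' negative-binomial stabilizer for the model's dispersion trend, so that the
#' variance of the output is approximately independent of the mean. The
#' transform is strictly increasing and behaves like log2(q) for large q.
#'
#' @param counts Gene x sample count matrix (training samples of `model`, or
#'   any matrix with matching gene ids when `size_factors` is supplied).
#' @param model A `cfrna_norm` object.
#' @param size_factors Optional size factors overriding the model's (used by
#'   [project_new_samples()]).
#' @return Matrix of transformed values, same dimnames as `counts`.
#' @export
vst <- function(counts, model, size_factors = NULL) {
  stopifnot(inherits(model, "cfrna_norm"))
  assert_count_matrix(counts)
  if (!identical(rownames(counts), model$gene_ids))
    stop("gene ids of counts do not match the normalization model")
  s <- size_factors %||% model$size_factors[colnames(counts)]
  if (any(is.na(s))) stop("size factors unavailable for some samples")
  q <- sweep(counts, 2, s, "/")
  out <- vst_transform_q(q, model$trend["a0"], model$trend["a1"])
  dimnames(out) <- dimnames(counts)
  out
}

#' Project new samples through a trained normalization model
#'
#' Each new sample's size factor is the median of its counts divided by the
#' training pseudo-reference over usable genes; the training dispersion trend
#' is then applied via [vst()]. Dispersions are never refit, and each
#' sample's output is independent of which other new samples are present.
#'
#' @param model A `cfrna_norm` object.
#' @param counts_new Gene x sample count matrix on the model's gene space.
#' @return List with `vst` (transformed matrix) and `size_factors`.
#' @export
project_new_samples <- function(model, counts_new) {
  stopifnot(inherits(model, "cfrna_norm"))
  assert_count_matrix(counts_new, "counts_new")
  if (!identical(rownames(counts_new), model$gene_ids))
    stop("gene ids of counts_new do not match the normalization model")
  usable <- !is.na(model$pseudo_reference)
  if (sum(usable) < 50)
    stop("fewer than 50 usable genes overlap the training pseudo-reference")
  ref <- model$pseudo_reference[usable]
  s_new <- apply(counts_new[usable, , drop = FALSE] / ref, 2, stats::median)
  u <- vst(counts_new, model, size_factors = s_new)
  list(vst = u, size_factors = stats::setNames(s_new, colnames(counts_new)))
}

#' @export
#' @rdname vst
predict.cfrna_norm <- function(object, newdata, ...) {
  project_new_samples(object, newdata)$vst
}

#' Serialize / restore a normalization model as JSON
#'
#' @param model A `cfrna_norm` object.
#' @param path File path.
#' @return `read_normalization_model` returns the restored `cfrna_norm`.
#' @export
write_normalization_model <- function(model, path) {
  stopifnot(inherits(model, "cfrna_norm"))
  obj <- list(version = model$version,
              gene_ids = model$gene_ids,
              size_factors = as.list(model$size_factors),
              pseudo_reference = unname(model$pseudo_reference),
              dispersions = unname(model$dispersions),
              gene_means = unname(model$gene_means),
              trend = as.list(model$trend))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @export
#' @rdname write_normalization_model
read_normalization_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pseudo <- as.numeric(obj$pseudo_reference)
  structure(list(size_factors = unlist(obj$size_factors),
                 pseudo_reference = stats::setNames(pseudo, obj$gene_ids),
                 dispersions = stats::setNames(as.numeric(obj$dispersions),
                                               obj$gene_ids),
                 trend = unlist(obj$trend),
                 gene_means = stats::setNames(as.numeric(obj$gene_means),
                                              obj$gene_ids),
                 gene_ids = obj$gene_ids, version = obj$version),
            class = "cfrna_norm")
}
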