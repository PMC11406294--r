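#' ROC-AUC of classification scores
#'
#' Trapezoidal area under the ROC curve with midrank tie handling: the
#' probability that a positive-class score exceeds a negative-class score,
#' ties counting one half. Invariant under strictly increasing transforms of
#' the scores.
#'
#' @param scores Numeric scores (higher = more positive-class).
#' @param labels Per-sample labels with two classes.
#' @param positive_class Which label is positive; defaults to the
#'   lexicographically larger one.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive_class = NULL) {
  labels <- as.character(labels)
  positive_class <- positive_class %||% max(sort(unique(labels)))
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) stop("both classes must be present")
  auc_ustat(scores[pos], scores[!pos])
}

#' Youden's index threshold
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' scores plus -Inf and +Inf; samples scoring above the threshold are called
#' positive. Returns the candidate maximizing J = sensitivity +
#' specificity - 1, ties broken toward the lowest threshold.
#'
#' @inheritParams roc_auc
#' @return The threshold (numeric scalar).
#' @export
youden_threshold <- function(scores, labels, positive_class = NULL) {
  labels <- as.character(labels)
  positive_class <- positive_class %||% max(sort(unique(labels)))
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) == 1) {
    warning("all scores identical; Youden J = 0, returning the common score")
    return(u)
  }
  cand <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  j <- vapply(cand, function(t) {
    sens <- mean(scores[pos] > t)
    spec <- mean(scores[!pos] <= t)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]  # which.max takes the first (lowest) maximizer
}

# Standardize columns using training means/sds (constant columns get sd 1).
standardize_fit <- function(X) {
  m <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(means = m, sds = sd)
}
standardize_apply <- function(X, std) {
  sweep(sweep(X, 2, std$means, "-"), 2, std$sds, "/")
}

# Stratified CV fold ids (1..n_folds), seeded.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# Lambda grid: 100 log-spaced values from lambda_max (smallest lambda with
# all-zero coefficients) down to lambda_max * 1e-4.
lambda_grid_logistic <- function(Xs, y01, alpha, n_lambda = 100) {
  n <- nrow(Xs)
  g <- abs(crossprod(Xs, y01 - mean(y01))) / n
  lmax <- max(g) / max(alpha, 1e-3)
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = n_lambda))
}

#' Train an elastic-net regularized logistic classifier
#'
#' Features are standardized on the training data (means/sds stored and
#' reapplied to held-out data). The penalized objective is the negative mean
#' binomial log-likelihood plus `lambda * ((1 - alpha)/2 ||beta||_2^2 +
#' alpha ||beta||_1)` with an unpenalized intercept, fit with glmnet over a
#' 100-point log-spaced lambda grid; lambda is chosen to maximize mean
#' cross-validated AUC (stratified folds), ties toward the more regularized
#' end. The final model is refit on all training data at the chosen lambda
#' and a Youden threshold is derived from the training scores.
#'
#' @param X Samples x features numeric matrix (VST values on a gene panel).
#' @param y Binary labels (factor or character).
#' @param alpha Elastic-net mixing: 1 = lasso, 0 = ridge.
#' @param n_folds Cross-validation folds.
#' @param lambda Optional lambda grid overriding the default.
#' @param positive_class Defaults to the lexicographically larger label.
#' @param seed Integer seed for fold assignment.
#' @return A `cfrna_logit` model.
#' @export
train_regularized_logistic <- function(X, y, alpha = 1, n_folds = 5,
                                       lambda = NULL, positive_class = NULL,
                                       seed = 1L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("y must contain exactly two classes")
  if (ncol(X) < 1) stop("empty feature panel")
  positive_class <- positive_class %||% classes[2]
  y01 <- as.numeric(y == positive_class)

  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  grid <- lambda %||% lambda_grid_logistic(Xs, y01, alpha)
  grid <- sort(grid, decreasing = TRUE)

  cv_auc <- rep(0, length(grid))
  if (length(grid) > 1) {
    fold <- stratified_folds(y01, n_folds, seed)
    aucs <- matrix(NA_real_, n_folds, length(grid))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- glmnet::glmnet(Xs[tr, , drop = FALSE], y01[tr],
                            family = "binomial", alpha = alpha,
                            lambda = grid, standardize = FALSE)
      pr <- stats::predict(fit, Xs[!tr, , drop = FALSE], s = grid,
                           type = "response")
      held <- y01[!tr]
      if (length(unique(held)) == 2)
        aucs[f, ] <- apply(pr, 2, function(p)
          auc_ustat(p[held == 1], p[held == 0]))
    }
    cv_auc <- colMeans(aucs, na.rm = TRUE)
    cv_auc[is.na(cv_auc)] <- 0
  }
  fit <- glmnet::glmnet(Xs, y01, family = "binomial", alpha = alpha,
                        lambda = grid, standardize = FALSE)
  # lambda maximizing mean CV AUC; among ties, prefer lambdas whose
  # full-data fit is not intercept-only (a constant classifier cannot
  # realize the tied CV AUC), then take the most regularized
  tied <- which(cv_auc >= max(cv_auc) - 1e-12)
  nontrivial <- tied[fit$df[tied] > 0]
  best <- if (length(nontrivial)) nontrivial[1] else tied[1]
  beta <- as.numeric(stats::coef(fit, s = grid[best]))
  names(beta) <- c("(Intercept)", colnames(X))

  model <- structure(list(algorithm = if (alpha == 1) "lasso_logistic"
                          else if (alpha == 0) "ridge_logistic"
                          else "elasticnet_logistic",
                          alpha = alpha, lambda = grid[best],
                          lambda_grid = grid, cv_auc = cv_auc,
                          coefficients = beta, std = std,
                          gene_panel = colnames(X),
                          positive_class = positive_class,
                          negative_class = setdiff(classes, positive_class),
                          selected_genes = colnames(X)[beta[-1] != 0]),
                     class = "cfrna_logit")
  train_scores <- predict(model, X, type = "prob")
  model$youden_threshold <- suppressWarnings(
    youden_threshold(train_scores, y, positive_class))
  model
}

#' @export
predict.cfrna_logit <- function(object, newdata,
                                type = c("prob", "link", "class"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$gene_panel, colnames(newdata))
  if (length(miss)) stop("panel genes missing from input: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  Xs <- standardize_apply(newdata[, object$gene_panel, drop = FALSE],
                          object$std)
  eta <- drop(object$coefficients[1] + Xs %*% object$coefficients[-1])
  switch(type,
         link = eta,
         prob = stats::plogis(eta),
         class = ifelse(stats::plogis(eta) > object$youden_threshold,
                        object$positive_class, object$negative_class))
}

#' @export
print.cfrna_logit <- function(x, ...) {
  cat(x$algorithm, "classifier:", length(x$gene_panel), "panel genes,",
      length(x$selected_genes), "selected;",
      sprintf("lambda = %.4g; positive class = %s\n", x$lambda,
              x$positive_class))
  invisible(x)
}

#' @export
coef.cfrna_logit <- function(object, ...) object$coefficients
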