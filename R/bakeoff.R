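# Model bake-off harness: several classification algorithms trained under a
# shared contract (5-fold CV grid search on the training set), compared by
# validation AUC. The test set is never touched here.

# Generic CV grid search: returns the grid row with highest mean fold AUC.
cv_select <- function(X, y01, grid, fit_fun, score_fun, n_folds, seed) {
  if (nrow(grid) == 1) return(grid[1, , drop = FALSE])
  fold <- stratified_folds(y01, n_folds, seed)
  mean_auc <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      if (length(unique(y01[!tr])) < 2) return(NA_real_)
      m <- fit_fun(X[tr, , drop = FALSE], y01[tr], grid[g, , drop = FALSE],
                   child_seed(seed, 7 * g + f))
      sc <- score_fun(m, X[!tr, , drop = FALSE])
      auc_ustat(sc[y01[!tr] == 1], sc[y01[!tr] == 0])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  grid[which.max(mean_auc), , drop = FALSE]
}

#' Bake-off algorithm registry
#'
#' The required set: lasso- and ridge-regularized logistic regression,
#' random forest, linear-kernel SVM, k-nearest neighbors and naive Bayes.
#' Each entry provides `train(X, y01, n_folds, seed)` returning an object
#' with `score(newX)` (probability-like score for the positive class) and a
#' feature count. All features are standardized inside the wrappers where
#' the algorithm is scale-sensitive.
#'
#' @param ids Subset of algorithm ids to return.
#' @return Named list of algorithm definitions for [model_bakeoff()].
#' @export
bakeoff_algorithms <- function(ids = c("lasso_logistic", "ridge_logistic",
                                       "random_forest", "svm_linear",
                                       "knn", "naive_bayes")) {
  glmnet_entry <- function(alpha) {
    function(X, y01, n_folds, seed) {
      y <- ifelse(y01 == 1, "pos", "neg")
      m <- train_regularized_logistic(X, y, alpha = alpha, n_folds = n_folds,
                                      positive_class = "pos", seed = seed)
      list(score = function(newX) predict(m, newX, type = "prob"),
           n_features = length(m$selected_genes))
    }
  }
  all <- list(
    lasso_logistic = glmnet_entry(1),
    ridge_logistic = glmnet_entry(0),
    random_forest = function(X, y01, n_folds, seed) {
      grid <- data.frame(mtry = unique(pmax(1, c(
        floor(sqrt(ncol(X))), floor(ncol(X) / 3)))))
      fit_fun <- function(X, y, p, s) with_seed(s,
        randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                   ntree = 300, mtry = p$mtry))
      score_fun <- function(m, X) stats::predict(m, X, type = "prob")[, "1"]
      best <- cv_select(X, y01, grid, fit_fun, score_fun, n_folds, seed)
      m <- fit_fun(X, y01, best, child_seed(seed, 1))
      list(score = function(newX) score_fun(m, newX),
           n_features = ncol(X))
    },
    svm_linear = function(X, y01, n_folds, seed) {
      std <- standardize_fit(X)
      Xs <- standardize_apply(X, std)
      grid <- data.frame(cost = c(0.01, 0.1, 1, 10))
      fit_fun <- function(X, y, p, s) {
        m <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                        cost = p$cost, scale = FALSE)
        # orient decision values toward the positive class
        dv <- attr(stats::predict(m, X, decision.values = TRUE),
                   "decision.values")[, 1]
        flip <- auc_ustat(dv[y == 1], dv[y == 0]) < 0.5
        list(m = m, sign = if (flip) -1 else 1)
      }
      score_fun <- function(m, X) m$sign * attr(
        stats::predict(m$m, X, decision.values = TRUE),
        "decision.values")[, 1]
      best <- cv_select(Xs, y01, grid, fit_fun, score_fun, n_folds, seed)
      m <- fit_fun(Xs, y01, best, seed)
      list(score = function(newX) score_fun(m, standardize_apply(newX, std)),
           n_features = ncol(X))
    },
    knn = function(X, y01, n_folds, seed) {
      std <- standardize_fit(X)
      Xs <- standardize_apply(X, std)
      grid <- data.frame(k = c(5, 11, 21))
      fit_fun <- function(X, y, p, s) list(X = X, y = y, k = p$k, seed = s)
      score_fun <- function(m, newX) {
        with_seed(m$seed, {
          pr <- class::knn(m$X, newX, factor(m$y, levels = c(0, 1)),
                           k = min(m$k, nrow(m$X)), prob = TRUE)
          p_win <- attr(pr, "prob")
          ifelse(pr == "1", p_win, 1 - p_win)
        })
      }
      best <- cv_select(Xs, y01, grid, fit_fun, score_fun, n_folds, seed)
      m <- fit_fun(Xs, y01, best, seed)
      list(score = function(newX) score_fun(m, standardize_apply(newX, std)),
           n_features = ncol(X))
    },
    naive_bayes = function(X, y01, n_folds, seed) {
      m <- e1071::naiveBayes(as.data.frame(X), factor(y01, levels = c(0, 1)))
      list(score = function(newX)
             stats::predict(m, as.data.frame(newX), type = "raw")[, "1"],
           n_features = ncol(X))
    })
  all[ids]
}

#' Compare classification algorithms on a validation set
#'
#' Each algorithm is trained on the training set with 5-fold CV grid search
#' over its hyperparameters, then scored on the validation set. The chosen
#' model is the one with the highest validation AUC (ties broken toward
#' fewer used features, then algorithm id order). The test set plays no role
#' in this operation.
#'
#' @param X_train,X_val Samples x features matrices (same panel).
#' @param y_train,y_val Binary labels.
#' @param algorithms From [bakeoff_algorithms()].
#' @param positive_class Defaults to the lexicographically larger label.
#' @param n_folds CV folds.
#' @param seed Integer seed.
#' @return List: `table` (data.frame algorithm / validation_auc /
#'   n_features), `chosen` (algorithm id), `model` (the chosen trained
#'   model; call `model$score(newX)` for scores), `positive_class`.
#' @export
model_bakeoff <- function(X_train, y_train, X_val, y_val,
                          algorithms = bakeoff_algorithms(),
                          positive_class = NULL, n_folds = 5, seed = 1L) {
  if (!length(algorithms)) stop("algorithm set must be non-empty")
  y_train <- as.character(y_train); y_val <- as.character(y_val)
  classes <- sort(unique(c(y_train, y_val)))
  if (length(unique(y_val)) < 2) stop("validation set must contain both classes")
  positive_class <- positive_class %||% classes[2]
  ytr <- as.numeric(y_train == positive_class)
  yva <- as.numeric(y_val == positive_class)

  fits <- vector("list", length(algorithms))
  names(fits) <- names(algorithms)
  tab <- data.frame(algorithm = names(algorithms),
                    validation_auc = NA_real_, n_features = NA_integer_)
  for (i in seq_along(algorithms)) {
    fits[[i]] <- algorithms[[i]](X_train, ytr, n_folds,
                                 child_seed(seed, 13 * i))
    sc <- fits[[i]]$score(X_val)
    tab$validation_auc[i] <- auc_ustat(sc[yva == 1], sc[yva == 0])
    tab$n_features[i] <- fits[[i]]$n_features
  }
  ord <- order(-tab$validation_auc, tab$n_features, tab$algorithm)
  chosen <- tab$algorithm[ord[1]]
  list(table = tab, chosen = chosen, model = fits[[chosen]],
       positive_class = positive_class)
}
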