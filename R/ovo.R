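#' Train a one-vs-one stacked multiclass classifier
#'
#' For each unordered pair of the four disease classes, a lasso-regularized
#' logistic model is trained on only that pair's training samples using the
#' pair's gene panel (the positive class of a pair is the lexicographically
#' larger label). Every pairwise model then scores ALL training samples —
#' including samples from classes outside the pair — yielding an n x C(k,2)
#' classification-score matrix (six columns for four classes), on which a
#' random-forest meta-classifier is trained against the multiclass labels.
#'
#' @param vst_train Genes x samples matrix of VST values (training set).
#' @param labels Class label per training sample (exactly the class set of
#'   the model; canonically KD, MIS-C, viral, bacterial).
#' @param per_pair_panels Named list of `cfrna_panel` (or character vectors)
#'   keyed `"A|B"` with A < B lexicographically, one per pair.
#' @param seed Integer seed (pairwise CV folds and the forest).
#' @param n_trees Trees in the meta-classifier (default 500; sqrt(p)
#'   features per split).
#' @return A `cfrna_ovo` model.
#' @export
train_ovo_stack <- function(vst_train, labels, per_pair_panels, seed = 1L,
                            n_trees = 500) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  pair_keys <- vapply(pairs, paste, "", collapse = "|")
  miss <- setdiff(pair_keys, names(per_pair_panels))
  if (length(miss)) stop("missing pair panel(s): ", paste(miss, collapse = ", "))

  Xall <- t(vst_train)
  pair_models <- vector("list", length(pairs))
  names(pair_models) <- pair_keys
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    panel <- per_pair_panels[[pair_keys[i]]]
    genes <- if (inherits(panel, "cfrna_panel")) panel$gene_ids else panel
    in_pair <- labels %in% pr
    pair_models[[i]] <- train_regularized_logistic(
      Xall[in_pair, genes, drop = FALSE], labels[in_pair], alpha = 1,
      positive_class = pr[2], seed = child_seed(seed, 31 * i))
  }

  scores <- ovo_score_matrix(pair_models, Xall)
  rf <- with_seed(child_seed(seed, 997),
                  randomForest::randomForest(
                    scores, factor(labels, levels = classes),
                    ntree = n_trees,
                    mtry = max(1, floor(sqrt(ncol(scores))))))
  structure(list(classes = classes, pair_models = pair_models,
                 meta = rf, n_trees = n_trees, seed = seed),
            class = "cfrna_ovo")
}

# n x C(k,2) matrix of pairwise positive-class probabilities.
ovo_score_matrix <- function(pair_models, X) {
  scores <- vapply(pair_models, function(m) predict(m, X, type = "prob"),
                   numeric(nrow(X)))
  if (nrow(X) == 1) scores <- matrix(scores, nrow = 1,
                                     dimnames = list(rownames(X),
                                                     names(pair_models)))
  scores
}

#' Predict class probabilities from a one-vs-one stack
#'
#' Computes the pairwise score vector for each sample and passes it through
#' the random-forest meta-classifier. Probabilities sum to 1 per sample; the
#' predicted class is the argmax (ties broken by lexicographic class order).
#' The full probability vector is retained for reporting.
#'
#' @param model A `cfrna_ovo` model.
#' @param vst_new Genes x samples VST matrix produced by
#'   [project_new_samples()] with the training normalization model.
#' @return List: `probabilities` (samples x classes), `predicted` (named
#'   character), `scores` (the pairwise score matrix), `ranked` (list of
#'   class orderings by descending probability).
#' @export
predict_multiclass <- function(model, vst_new) {
  stopifnot(inherits(model, "cfrna_ovo"))
  needed <- unique(unlist(lapply(model$pair_models, `[[`, "gene_panel")))
  miss <- setdiff(needed, rownames(vst_new))
  if (length(miss)) stop("panel genes missing from input: ",
                         paste(utils::head(miss, 10), collapse = ", "))
  X <- t(vst_new)
  scores <- ovo_score_matrix(model$pair_models, X)
  prob <- stats::predict(model$meta, scores, type = "prob")
  prob <- prob / rowSums(prob)
  predicted <- apply(prob, 1, function(p) {
    top <- which(p == max(p))
    colnames(prob)[top[order(colnames(prob)[top])[1]]]
  })
  ranked <- apply(prob, 1, function(p)
    colnames(prob)[order(-p, colnames(prob))], simplify = FALSE)
  list(probabilities = prob,
       predicted = stats::setNames(predicted, rownames(prob)),
       scores = scores, ranked = ranked)
}

#' @export
predict.cfrna_ovo <- function(object, newdata, ...) {
  predict_multiclass(object, newdata)
}

#' @export
print.cfrna_ovo <- function(x, ...) {
  cat("One-vs-one stacked classifier:", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), "),",
      length(x$pair_models), "pairwise lasso models,",
      x$n_trees, "meta-forest trees\n")
  invisible(x)
}
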