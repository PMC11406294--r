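#' End-to-end multiclass diagnostic pipeline
#'
#' Runs the full analysis on a cohort: QC filtering, stratified 70:30
#' train/test partitioning of the four disease classes, normalization fitted
#' on the training set only, pairwise differential abundance and gene-panel
#' selection on the training set, one-vs-one stacked multiclass training,
#' projection of the test set through the training normalization model,
#' cell-type deconvolution, healthy-donor organ statistics, and a diagnostic
#' report for every passing test sample.
#'
#' @param cohort A `cfrna_cohort` (or a list with `counts`, `metadata`,
#'   and a `reference` for deconvolution).
#' @param classes The disease classes to classify (default the four of the
#'   multiclass framework).
#' @param ratios Train/test split ratios.
#' @param panel_criteria Filter cascade for the pairwise panels.
#' @param seed Integer seed.
#' @param n_trees Meta-forest size.
#' @return A `cfrna_pipeline` list with all intermediate objects, per-test-
#'   sample reports, and train/test accuracy.
#' @export
run_pipeline <- function(cohort,
                         classes = c("KD", "MIS-C", "viral", "bacterial"),
                         ratios = c(train = 70, test = 30),
                         panel_criteria = panel_preset("multiclass_pairwise"),
                         seed = 1L, n_trees = 500) {
  md <- cohort$metadata
  qc <- apply_qc(md)
  passing <- qc$sample_id[qc$pass]
  md_pass <- md[md$sample_id %in% passing, ]

  md_cls <- md_pass[md_pass$group %in% classes, ]
  assignment <- stratified_partition(
    md_cls, ratios, strata = c("group", "hospital", "subgroup"),
    seed = child_seed(seed, 1))
  train_ids <- names(assignment)[assignment == "train"]
  test_ids <- names(assignment)[assignment == "test"]

  counts_train <- cohort$counts[, train_ids, drop = FALSE]
  norm <- fit_normalization(counts_train)
  labels <- stats::setNames(md_cls$group, md_cls$sample_id)

  pairs <- utils::combn(sort(classes), 2, simplify = FALSE)
  panels <- list()
  de_results <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "|")
    ids <- train_ids[labels[train_ids] %in% pr]
    de <- run_de(cohort$counts[, ids, drop = FALSE], norm,
                 labels[ids], group_a = pr[1], group_b = pr[2])
    de_results[[key]] <- de
    panels[[key]] <- select_panel(de, panel_criteria, name = key)
  }

  vst_train <- vst(counts_train, norm)
  ovo <- train_ovo_stack(vst_train, labels[train_ids], panels,
                         seed = child_seed(seed, 2), n_trees = n_trees)
  train_pred <- predict_multiclass(ovo, vst_train)

  vst_test <- project_new_samples(norm, cohort$counts[, test_ids,
                                                      drop = FALSE])$vst
  test_pred <- predict_multiclass(ovo, vst_test)

  fractions <- deconvolve(cohort$counts[, md_pass$sample_id, drop = FALSE],
                          cohort$reference)
  healthy_ids <- md_pass$sample_id[md_pass$group == "healthy"]
  hstats <- healthy_stats(fractions, healthy_ids)
  zs <- organ_zscores(fractions[test_ids, , drop = FALSE], hstats)

  reports <- lapply(test_ids, function(sid) {
    z <- zs[sid, ]
    attr(z, "low_confidence") <- attr(zs, "low_confidence")
    build_report(sid, test_pred$probabilities[sid, ], z, qc_status = "pass")
  })
  names(reports) <- test_ids

  structure(list(qc = qc, assignment = assignment, norm_model = norm,
                 de_results = de_results, panels = panels, ovo = ovo,
                 train_pred = train_pred, test_pred = test_pred,
                 train_accuracy = mean(train_pred$predicted ==
                                         labels[train_ids]),
                 test_accuracy = mean(test_pred$predicted ==
                                        labels[test_ids]),
                 fractions = fractions, healthy_stats = hstats,
                 reports = reports, labels = labels),
            class = "cfrna_pipeline")
}

#' @export
print.cfrna_pipeline <- function(x, ...) {
  cat("cfRNA diagnostic pipeline:",
      sum(x$assignment == "train"), "train /",
      sum(x$assignment == "test"), "test samples;",
      length(x$panels), "pairwise panels\n")
  cat(sprintf("  train accuracy = %.3f; test accuracy = %.3f\n",
              x$train_accuracy, x$test_accuracy))
  invisible(x)
}

#' Binary KD vs MIS-C classification path
#'
#' QC-passing KD and MIS-C samples are partitioned 60:20:20 into train,
#' validation and test (stratified by group, hospital and subgroup);
#' normalization and differential abundance use the training set only; the
#' filter cascade produces the model's gene panel; one or more algorithms
#' are trained with 5-fold CV grid search and the validation AUC selects the
#' final model, which is then evaluated once on the untouched test set with
#' the training-derived Youden threshold.
#'
#' @param cohort A `cfrna_cohort`.
#' @param criteria Panel filter criteria (default the misc_kd preset).
#' @param algorithms Algorithm ids for [bakeoff_algorithms()]; a single id
#'   skips the bake-off comparison table semantics but uses the same path.
#' @param groups Length-2 character vector (group A, group B = positive).
#' @param seed Integer seed.
#' @return List with the chosen model, panel, per-set AUCs, Youden threshold
#'   and test-set calls.
#' @export
run_binary_path <- function(cohort, criteria = panel_preset("misc_kd"),
                            algorithms = "lasso_logistic",
                            groups = c("KD", "MIS-C"), seed = 1L) {
  md <- cohort$metadata
  qc <- apply_qc(md)
  md2 <- md[md$sample_id %in% qc$sample_id[qc$pass] & md$group %in% groups, ]
  assignment <- stratified_partition(
    md2, c(train = 60, validation = 20, test = 20),
    strata = c("group", "hospital", "subgroup"), seed = child_seed(seed, 3))
  ids <- split(names(assignment), assignment)
  labels <- stats::setNames(md2$group, md2$sample_id)

  counts_train <- cohort$counts[, ids$train, drop = FALSE]
  norm <- fit_normalization(counts_train)
  de <- run_de(counts_train, norm, labels[ids$train],
               group_a = groups[1], group_b = groups[2])
  panel <- select_panel(de, criteria, name = paste(groups, collapse = "_vs_"))

  feat <- function(set_ids) {
    u <- project_new_samples(norm, cohort$counts[, set_ids, drop = FALSE])$vst
    t(u)[, panel$gene_ids, drop = FALSE]
  }
  X_train <- feat(ids$train); X_val <- feat(ids$validation)
  X_test <- feat(ids$test)

  bake <- model_bakeoff(X_train, labels[ids$train], X_val,
                        labels[ids$validation],
                        algorithms = bakeoff_algorithms(algorithms),
                        positive_class = groups[2],
                        seed = child_seed(seed, 4))
  score <- bake$model$score
  y01 <- function(set_ids) as.numeric(labels[set_ids] == groups[2])

  train_scores <- score(X_train)
  thr <- suppressWarnings(youden_threshold(train_scores, labels[ids$train],
                                           positive_class = groups[2]))
  aucs <- c(train = auc_ustat(train_scores[y01(ids$train) == 1],
                              train_scores[y01(ids$train) == 0]),
            validation = auc_ustat(score(X_val)[y01(ids$validation) == 1],
                                   score(X_val)[y01(ids$validation) == 0]),
            test = auc_ustat(score(X_test)[y01(ids$test) == 1],
                             score(X_test)[y01(ids$test) == 0]))
  test_scores <- score(X_test)
  list(bakeoff = bake, panel = panel, norm_model = norm, de = de,
       assignment = assignment, auc = aucs, youden_threshold = thr,
       test_scores = test_scores,
       test_calls = ifelse(test_scores > thr, groups[2], groups[1]),
       test_labels = labels[ids$test])
}
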