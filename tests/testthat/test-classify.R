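test_that("stratified partitioning hits exact ratios and is seeded", {
  md <- data.frame(sample_id = sprintf("s%03d", 1:100),
                   group = rep("KD", 100))
  a <- stratified_partition(md, c(train = 60, validation = 20, test = 20),
                            strata = "group", seed = 5)
  expect_equal(unname(table(a)[c("train", "validation", "test")]),
               c(60, 20, 20), ignore_attr = TRUE)

  md10 <- data.frame(sample_id = sprintf("s%02d", 1:10),
                     group = rep("KD", 10))
  a10 <- stratified_partition(md10, c(train = 70, test = 30),
                              strata = "group", seed = 5)
  expect_equal(sum(a10 == "train"), 7)
  expect_equal(sum(a10 == "test"), 3)

  b <- stratified_partition(md, c(train = 60, validation = 20, test = 20),
                            strata = "group", seed = 5)
  expect_identical(a, b)

  # tiny stratum cells collapse to group-only cells with a warning
  md_small <- data.frame(sample_id = sprintf("s%02d", 1:20),
                         group = rep(c("KD", "MIS-C"), each = 10),
                         hospital = c(rep("H1", 18), "H2", "H3"))
  expect_warning(
    a2 <- stratified_partition(md_small, c(train = 70, test = 30),
                               strata = c("group", "hospital"), seed = 5),
    "collapsed")
  expect_equal(sum(a2 == "train"), 14)
})

test_that("full shrinkage collapses to the intercept-only classifier", {
  with_seed(81, {
    X <- matrix(rnorm(60 * 10), 60, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
  })
  y <- rep(c("neg", "pos"), c(20, 40))
  m <- suppressWarnings(
    train_regularized_logistic(X, y, alpha = 1, lambda = 1e3))
  expect_true(all(m$coefficients[-1] == 0))
  expect_equal(unname(m$coefficients[1]), log(40 / 20), tolerance = 1e-6)
  expect_length(m$selected_genes, 0)
})

test_that("lasso finds a planted informative feature among noise", {
  with_seed(82, {
    X <- matrix(rnorm(200 * 50), 200, 50,
                dimnames = list(NULL, paste0("f", 1:50)))
    y <- rep(c("a", "b"), each = 100)
    X[y == "b", 1] <- X[y == "b", 1] + 2
  })
  m <- train_regularized_logistic(X, y, alpha = 1, seed = 3)
  beta <- m$coefficients[-1]
  expect_gt(abs(beta["f1"]), 0)
  expect_equal(names(which.max(abs(beta))), "f1")
  expect_true("f1" %in% m$selected_genes)
})

test_that("predicted probabilities follow the logistic formula", {
  with_seed(83, {
    X <- matrix(rnorm(80 * 5), 80, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rep(c("a", "b"), each = 40)
    X[y == "b", 2] <- X[y == "b", 2] + 1.5
  })
  m <- train_regularized_logistic(X, y, alpha = 0.5, seed = 4)
  Xs <- sweep(sweep(X, 2, m$std$means, "-"), 2, m$std$sds, "/")
  manual <- plogis(m$coefficients[1] + drop(Xs %*% m$coefficients[-1]))
  expect_equal(unname(predict(m, X, type = "prob")), unname(manual),
               tolerance = 1e-12)
})

test_that("lasso sparsity grows monotonically down the lambda path", {
  with_seed(84, {
    X <- matrix(rnorm(100 * 30), 100, 30,
                dimnames = list(NULL, paste0("f", 1:30)))
    y <- rep(c("a", "b"), each = 50)
    X[y == "b", 1:5] <- X[y == "b", 1:5] + 1
  })
  fit <- glmnet::glmnet(scale(X), as.numeric(y == "b"), family = "binomial",
                        alpha = 1,
                        lambda = cfrnadx:::lambda_grid_logistic(
                          scale(X), as.numeric(y == "b"), 1),
                        standardize = FALSE)
  df <- fit$df  # nonzero count along decreasing lambda
  expect_equal(df[1], 0)
  expect_true(all(df <= 30))
  # weakly increasing as lambda decreases, allowing the small active-set
  # fluctuations coordinate descent shows near saturation
  expect_true(all(cummax(df) - df <= 5))
  expect_gt(cor(seq_along(df), df, method = "spearman"), 0.8)
})

test_that("Youden threshold matches exhaustive candidate search", {
  expect_equal(youden_threshold(c(0.8, 0.9, 0.1, 0.2),
                                c("pos", "pos", "neg", "neg"),
                                positive_class = "pos"), 0.5)
  expect_warning(t0 <- youden_threshold(rep(0.4, 6),
                                        rep(c("pos", "neg"), 3),
                                        positive_class = "pos"),
                 "identical")
  expect_equal(t0, 0.4)

  with_seed(85, {
    for (rep in 1:50) {
      n <- sample(6:20, 1)
      scores <- round(runif(n), 2)
      labels <- sample(c("pos", "neg"), n, replace = TRUE)
      if (length(unique(labels)) < 2 || length(unique(scores)) < 2) next
      t <- youden_threshold(scores, labels, positive_class = "pos")
      u <- sort(unique(scores))
      cand <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
      j <- sapply(cand, function(th)
        mean(scores[labels == "pos"] > th) +
          mean(scores[labels == "neg"] <= th) - 1)
      expect_equal(t, cand[which.max(j)])
      # the returned threshold attains the maximal J
      jt <- mean(scores[labels == "pos"] > t) +
        mean(scores[labels == "neg"] <= t) - 1
      expect_equal(jt, max(j))
    }
  })
})

test_that("roc_auc equals all-pairs enumeration and is rank-invariant", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c("n", "n", "p", "p"),
                       positive_class = "p"), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c("n", "n", "p", "p"),
                       positive_class = "p"), 0)
  with_seed(86, {
    for (rep in 1:100) {
      n_p <- sample(2:8, 1); n_n <- sample(2:8, 1)
      sc <- sample(1:6, n_p + n_n, replace = TRUE)
      lab <- rep(c("p", "n"), c(n_p, n_n))
      brute <- mean(outer(sc[lab == "p"], sc[lab == "n"], function(a, b)
        (a > b) + 0.5 * (a == b)))
      expect_equal(roc_auc(sc, lab, positive_class = "p"), brute,
                   tolerance = 1e-12)
      expect_equal(roc_auc(exp(3 * sc), lab, positive_class = "p"), brute,
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(1:3, rep("p", 3)), "both classes")
})

test_that("the bake-off selects by validation AUC deterministically", {
  with_seed(87, {
    X <- matrix(rnorm(120 * 20), 120, 20,
                dimnames = list(NULL, paste0("f", 1:20)))
    y <- rep(c("a", "b"), each = 60)
    X[y == "b", 1:3] <- X[y == "b", 1:3] + 1.5
    Xv <- matrix(rnorm(40 * 20), 40, 20,
                 dimnames = list(NULL, paste0("f", 1:20)))
    yv <- rep(c("a", "b"), each = 20)
    Xv[yv == "b", 1:3] <- Xv[yv == "b", 1:3] + 1.5
  })
  single <- model_bakeoff(X, y, Xv, yv,
                          algorithms = bakeoff_algorithms("lasso_logistic"),
                          seed = 2)
  expect_equal(single$chosen, "lasso_logistic")

  b1 <- model_bakeoff(X, y, Xv, yv,
                      algorithms = bakeoff_algorithms(
                        c("lasso_logistic", "ridge_logistic", "naive_bayes")),
                      seed = 2)
  b2 <- model_bakeoff(X, y, Xv, yv,
                      algorithms = bakeoff_algorithms(
                        c("lasso_logistic", "ridge_logistic", "naive_bayes")),
                      seed = 2)
  expect_identical(b1$table, b2$table)
  expect_equal(b1$table$validation_auc[b1$table$algorithm == b1$chosen],
               max(b1$table$validation_auc))
  expect_error(model_bakeoff(X, y, Xv, rep("a", 40), seed = 2),
               "both classes")
})

test_that("every required bake-off algorithm separates planted signal", {
  with_seed(88, {
    X <- matrix(rnorm(100 * 10), 100, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rep(c("a", "b"), each = 50)
    X[y == "b", 1:2] <- X[y == "b", 1:2] + 2
    Xv <- matrix(rnorm(60 * 10), 60, 10,
                 dimnames = list(NULL, paste0("f", 1:10)))
    yv <- rep(c("a", "b"), each = 30)
    Xv[yv == "b", 1:2] <- Xv[yv == "b", 1:2] + 2
  })
  bake <- model_bakeoff(X, y, Xv, yv, algorithms = bakeoff_algorithms(),
                        seed = 6)
  expect_equal(nrow(bake$table), 6)
  expect_true(all(bake$table$validation_auc > 0.8))
})
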