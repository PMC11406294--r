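test_that("Wald test is calibrated under the null", {
  de <- null_de()
  frac <- mean(de$p_value < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("Wald test recovers a planted one-unit log2 fold change", {
  mu <- exp(runif_det(2000, log(20), log(2000), seed = 53))
  counts_a <- nb_matrix(mu, 50, phi = 0.1, seed = 54)
  counts_b <- nb_matrix(2 * mu, 50, phi = 0.1, seed = 55)
  colnames(counts_b) <- sprintf("t%03d", 1:50)
  counts <- cbind(counts_a, counts_b)
  s <- setNames(rep(1, 100), colnames(counts))
  de <- nb_wald_test(counts, s, setNames(rep(0.1, 2000), rownames(counts)),
                     rep(c("A", "B"), each = 50))
  expect_lt(abs(median(de$log2fc, na.rm = TRUE) - 1), 0.1)
  expect_gt(mean(de$q_value < 0.05, na.rm = TRUE), 0.8)
})

test_that("per-gene fits agree with a single-gene GLM oracle", {
  skip_if_not_installed("MASS")
  mu <- exp(runif_det(15, log(20), log(500), seed = 56))
  counts_a <- nb_matrix(mu, 12, phi = 0.15, seed = 57)
  counts_b <- nb_matrix(mu * 2^runif_det(15, -1, 1, seed = 58), 12,
                        phi = 0.15, seed = 59)
  colnames(counts_b) <- sprintf("t%03d", 1:12)
  counts <- cbind(counts_a, counts_b) + 1  # keep fits comfortably interior
  s <- setNames(runif_det(24, 0.7, 1.4, seed = 60), colnames(counts))
  labels <- rep(c("A", "B"), each = 12)
  phi <- setNames(rep(0.15, 15), rownames(counts))
  de <- nb_wald_test(counts, s, phi, labels)
  x <- as.numeric(labels == "B")
  for (i in seq_len(15)) {
    g <- suppressWarnings(stats::glm(
      counts[i, ] ~ x + offset(log(s)),
      family = MASS::negative.binomial(theta = 1 / 0.15)))
    expect_equal(de$log2fc[i], unname(coef(g)["x"]) / log(2),
                 tolerance = 1e-4)
    se_glm <- sqrt(summary(g, dispersion = 1)$cov.scaled["x", "x"])
    expect_equal(de$se[i], se_glm / log(2), tolerance = 1e-3)
  }
})

test_that("degenerate genes get NA statistics and leave the BH family", {
  counts <- rbind(g1 = c(5, 7, 6, 9), g2 = c(0, 0, 0, 0),
                  g3 = c(9, 2, 8, 1))
  colnames(counts) <- paste0("s", 1:4)
  s <- setNames(rep(1, 4), colnames(counts))
  de <- nb_wald_test(counts, s, setNames(rep(0.1, 3), rownames(counts)),
                     c("A", "A", "B", "B"))
  expect_true(is.na(de$p_value[2]))
  ok <- !is.na(de$p_value)
  expect_equal(de$q_value[ok], p.adjust(de$p_value[ok], "BH"))
})

test_that("BH step-up matches hand evaluation and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- runif_det(200, 0, 1, seed = 61)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  # NAs excluded from the family size
  expect_equal(bh_adjust(c(0.01, NA, 0.04)),
               c(0.02, NA, 0.04))
})

test_that("gene AUC equals brute-force pair enumeration", {
  m <- rbind(g1 = c(1, 3, 2, 4))
  colnames(m) <- paste0("s", 1:4)
  expect_equal(unname(gene_auc(m, c("A", "A", "B", "B"))), 0.75)
  m2 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 5), g3 = c(4, 3, 2, 1))
  colnames(m2) <- paste0("s", 1:4)
  expect_equal(unname(gene_auc(m2, c("A", "A", "B", "B"))), c(1, 0.5, 0))

  with_seed(62, {
    for (rep in 1:100) {
      n_a <- sample(2:8, 1); n_b <- sample(2:8, 1)
      v <- sample(1:5, n_a + n_b, replace = TRUE)  # forces ties
      labels <- rep(c("A", "B"), c(n_a, n_b))
      mat <- matrix(v, 1, dimnames = list("g", paste0("s", seq_along(v))))
      a <- v[labels == "A"]; b <- v[labels == "B"]
      brute <- mean(outer(b, a, function(x, y)
        (x > y) + 0.5 * (x == y)))
      expect_equal(unname(gene_auc(mat, labels)), brute, tolerance = 1e-12)
    }
  })
})

test_that("label swap negates log2FC and reflects AUC", {
  mu <- exp(runif_det(200, log(20), log(500), seed = 63))
  counts <- nb_matrix(mu, 20, phi = 0.1, seed = 64)
  s <- setNames(rep(1, 20), colnames(counts))
  phi <- setNames(rep(0.1, 200), rownames(counts))
  labels <- rep(c("A", "B"), each = 10)
  de_ab <- nb_wald_test(counts, s, phi, labels, "A", "B")
  de_ba <- nb_wald_test(counts, s, phi, labels, "B", "A")
  expect_equal(de_ab$log2fc, -de_ba$log2fc, tolerance = 1e-6)
  auc_ab <- gene_auc(counts, labels, "A", "B")
  auc_ba <- gene_auc(counts, labels, "B", "A")
  expect_equal(unname(auc_ab), unname(1 - auc_ba), tolerance = 1e-12)
})

test_that("exclusive intersections follow UpSet semantics", {
  out <- intersect_dag_sets(list(A = c("g1", "g2"), B = c("g2", "g3")))
  get <- function(p) out$count[out$pattern == p]
  expect_equal(get("A"), 1)
  expect_equal(get("B"), 1)
  expect_equal(get("A&B"), 1)
  expect_equal(sum(out$count), 3)

  same <- intersect_dag_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$count[same$pattern == "A&B"], 2)
  expect_equal(sum(same$count), 2)

  disj <- intersect_dag_sets(list(A = "x", B = "y", C = "z"))
  expect_true(all(disj$count[disj$pattern %in% c("A", "B", "C")] == 1))
  expect_equal(sum(disj$count), 3)
  expect_error(intersect_dag_sets(list(A = "x")), "two")
  expect_error(intersect_dag_sets(setNames(list("x", "y"), c("A", "A"))),
               "unique")
})

test_that("the shared inflammation signature lands in the all-groups cell", {
  coh <- cached_fixture("shared_sig_cohort", {
    simulate_cohort(
      simulation_config(group_sizes = c("KD" = 30, "MIS-C" = 30,
                                        "viral" = 30, "bacterial" = 30,
                                        "healthy" = 30),
                        n_genes = 2000, qc_fail_fraction = 0, seed = 65),
      ref13_2000())
  })
  norm <- fit_normalization(coh$counts)
  labels <- setNames(coh$metadata$group, coh$metadata$sample_id)
  dgs <- c("KD", "MIS-C", "viral", "bacterial")
  sets <- lapply(dgs, function(g) {
    ids <- names(labels)[labels %in% c(g, "healthy")]
    de <- run_de(coh$counts[, ids], norm, labels[ids], "healthy", g)
    de$gene[which(de$q_value < 0.05)]
  })
  names(sets) <- dgs
  shared <- coh$truth$shared_signature
  in_all <- Reduce(intersect, sets)
  expect_gte(mean(shared %in% in_all), 0.9)
  # and the UpSet table's full-intersection cell contains them
  tab <- intersect_dag_sets(sets)
  full <- tab$count[tab$pattern == paste(dgs, collapse = "&")]
  expect_gte(full, 0.9 * length(shared))
})
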