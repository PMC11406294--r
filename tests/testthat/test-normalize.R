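toy_counts <- function() {
  m <- matrix(c(10, 20, 5, 80, 12,
                20, 40, 10, 160, 24,
                15, 25, 8, 100, 20,
                30, 60, 20, 240, 40), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  m
}

test_that("size factors equal hand-computed median-of-ratios", {
  m <- toy_counts()
  # independent hand evaluation of the formula
  expected <- numeric(4)
  for (j in 1:4) {
    ratios <- numeric(5)
    for (i in 1:5) {
      g <- prod(m[i, ])^(1 / 4)
      ratios[i] <- m[i, j] / g
    }
    expected[j] <- median(ratios)
  }
  expect_equal(unname(estimate_size_factors(m)), expected, tolerance = 1e-12)
})

test_that("size factors reproduce doubling and symmetry cases", {
  m <- matrix(c(4, 10, 7, 8, 20, 14), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  s <- estimate_size_factors(m)  # column b is exactly 2x column a
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  m2 <- cbind(a = c(3, 9, 1), b = c(3, 9, 1), c = c(3, 9, 1))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(m2)), c(1, 1, 1))

  m3 <- cbind(a = c(0, 5), b = c(5, 0))
  rownames(m3) <- paste0("g", 1:2)
  expect_error(estimate_size_factors(m3), "no usable genes")
})

test_that("dispersion estimation recovers Poisson and NB truth", {
  mu <- exp(seq(log(20), log(2000), length.out = 2000))
  pois <- with_seed(31, {
    m <- vapply(1:50, function(j) rpois(2000, mu), numeric(2000))
    dimnames(m) <- list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:50))
    m
  })
  fit <- fit_dispersion(pois, rep(1, 50))
  expect_lte(median(fit$dispersions), 0.01)
  expect_lte(fit$trend["a0"], 0.01)

  nb <- nb_matrix(mu, 50, phi = 0.2, seed = 32)
  fit2 <- fit_dispersion(nb, rep(1, 50))
  expect_gte(fit2$trend["a0"], 0.1)
  expect_lte(fit2$trend["a0"], 0.3)

  flat <- matrix(5, 20, 4, dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  expect_error(fit_dispersion(flat, rep(1, 4)), "unidentifiable")
})

test_that("VST matches the quadrature oracle up to affine calibration", {
  a0 <- 0.1; a1 <- 0.5
  h <- function(q) cfrnadx:::vst_transform_q(q, a0, a1)
  qs <- exp(seq(log(1), log(1e5), length.out = 40))
  # oracle: integral of 1/sqrt(v(mu)) from 1 to q, scaled to log2 units
  oracle <- vapply(qs, function(q)
    stats::integrate(function(mu) 1 / sqrt(mu * (1 + a1) + a0 * mu^2),
                     1, q, rel.tol = 1e-12)$value * sqrt(a0) / log(2),
    numeric(1))
  expect_lt(max(abs((h(qs) - h(1)) - oracle)), 1e-6)
})

test_that("VST is monotone and log2-like in the tail", {
  h <- function(q) cfrnadx:::vst_transform_q(q, 0.05, 1.2)
  qs <- c(0, 10^seq(-3, 6, by = 0.25))
  expect_true(all(diff(h(qs)) > 0))
  tail_offsets <- h(c(1e8, 1e10)) - log2(c(1e8, 1e10))
  expect_lt(abs(diff(tail_offsets)), 1e-3)
  expect_error(cfrnadx:::vst_transform_q(-1, 0.05, 1.2), "negative")
})

test_that("projection is train-consistent, pure and scale-equivariant", {
  coh <- binary_cohort()
  train <- coh$counts[, 1:40]
  model <- fit_normalization(train)
  u_train <- vst(train, model)

  # a copy of a training sample projects to its training transform
  proj <- project_new_samples(model, train[, 5, drop = FALSE])
  expect_lt(max(abs(proj$vst - u_train[, 5])), 1e-9)
  expect_lt(abs(proj$size_factors - model$size_factors[5]), 1e-9)

  # purity: alone vs inside a batch
  batch <- project_new_samples(model, coh$counts[, 41:120])
  solo <- project_new_samples(model, coh$counts[, 100, drop = FALSE])
  expect_identical(solo$vst[, 1], batch$vst[, colnames(coh$counts)[100]])

  # doubling a new sample's counts doubles its size factor, fixes its VST
  new1 <- coh$counts[, 60, drop = FALSE]
  new2 <- new1 * 2
  p1 <- project_new_samples(model, new1)
  p2 <- project_new_samples(model, new2)
  expect_equal(unname(p2$size_factors), unname(2 * p1$size_factors),
               tolerance = 1e-12)
  usable <- !is.na(model$pseudo_reference)
  expect_lt(max(abs(p2$vst[usable, 1] - p1$vst[usable, 1])), 1e-9)
})

test_that("VST flattens the mean-variance relationship where log2 does not", {
  a0 <- 0.005; a1 <- 2
  mu <- exp(seq(log(0.3), log(5000), length.out = 2000))
  phi <- a0 + a1 / mu
  counts <- with_seed(33, {
    m <- vapply(1:80, function(j) rnbinom(2000, mu = mu, size = 1 / phi),
                numeric(2000))
    dimnames(m) <- list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:80))
    m
  })
  model <- fit_normalization(counts)
  u <- vst(counts, model)
  q <- sweep(counts, 2, model$size_factors, "/")
  l <- log2(q + 1)
  bin_ratio <- function(x) {
    v <- apply(x, 1, var)
    bins <- findInterval(rank(mu) / length(mu), seq(0, 1, 0.1),
                         rightmost.closed = TRUE)
    mean(v[bins == 10]) / mean(v[bins == 1])
  }
  r_vst <- bin_ratio(u); r_log <- bin_ratio(l)
  r_vst <- max(r_vst, 1 / r_vst); r_log <- max(r_log, 1 / r_log)
  expect_lt(r_vst, 3)
  expect_gt(r_log, 30)
})

test_that("normalization models survive a JSON round trip", {
  counts <- nb_matrix(exp(seq(log(50), log(500), length.out = 60)), 8,
                      phi = 0.2, seed = 44)
  model <- fit_normalization(counts)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_normalization_model(model, path)
  back <- read_normalization_model(path)
  expect_equal(back$size_factors, model$size_factors)
  expect_equal(back$trend, model$trend)
  expect_equal(back$pseudo_reference, model$pseudo_reference)
  expect_equal(vst(counts, back), vst(counts, model))
})
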