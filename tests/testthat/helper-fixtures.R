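# Shared fixtures, built once per test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

ref13_2000 <- function() cached_fixture("ref13_2000",
  make_reference(13, 2000, seed = 5))

# Four disease classes + healthy, planted log2FC = 2 signatures.
four_class_cohort <- function() cached_fixture("four_class_cohort",
  simulate_cohort(
    simulation_config(group_sizes = c("KD" = 40, "MIS-C" = 40, "viral" = 40,
                                      "bacterial" = 40, "healthy" = 25),
                      n_genes = 2000, seed = 7),
    ref13_2000()))

# Binary KD / MIS-C cohort: 60 per class, planted log2FC = 2.
binary_cohort <- function() cached_fixture("binary_cohort",
  simulate_cohort(
    simulation_config(group_sizes = c("KD" = 60, "MIS-C" = 60,
                                      "healthy" = 10),
                      n_genes = 2000, qc_fail_fraction = 0, seed = 21),
    make_reference(13, 2000, seed = 6)))

# Null KD / MIS-C cohort: identical mixture concentrations for both groups
# and zero planted effect, so the two disease classes are exchangeable.
null_binary_cohort <- function() cached_fixture("null_binary_cohort", {
  alpha0 <- rep(2, 13)
  simulate_cohort(
    simulation_config(group_sizes = c("KD" = 60, "MIS-C" = 60,
                                      "healthy" = 10),
                      n_genes = 2000, qc_fail_fraction = 0,
                      signature_log2fc = 0, shared_signature_size = 0,
                      dirichlet_alpha = list("KD" = alpha0, "MIS-C" = alpha0,
                                             "healthy" = alpha0),
                      seed = 22),
    make_reference(13, 2000, seed = 6))
})

# 200-sample cohort for the end-to-end pipeline (40 per disease class,
# 30 healthy, 10 other hospitalized controls; 2,500 genes).
pipeline_cohort <- function() cached_fixture("pipeline_cohort",
  simulate_cohort(
    simulation_config(group_sizes = c("KD" = 40, "MIS-C" = 40, "viral" = 40,
                                      "bacterial" = 40, "healthy" = 30,
                                      "other" = 10),
                      n_genes = 2500, seed = 9),
    make_reference(13, 2500, seed = 8)))

pipeline_run <- function() cached_fixture("pipeline_run",
  suppressWarnings(run_pipeline(pipeline_cohort(), seed = 11)))

# Permissive filter criteria used for null / permutation controls, where the
# discovery cascade correctly returns nothing significant.
permissive_criteria <- function()
  list(q_max = 1, base_mean_min = 0, auc_min = NULL, abs_lfc_min = 0,
       top_n = 150)

# Simulate a plain NB count matrix (no mixtures) with given per-gene means
# and dispersion; columns get unit size factors.
nb_matrix <- function(mu, n, phi, seed) {
  with_seed(seed, {
    m <- vapply(seq_len(n), function(j)
      stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
      numeric(length(mu)))
    dimnames(m) <- list(sprintf("g%04d", seq_along(mu)),
                        sprintf("s%03d", seq_len(n)))
    m
  })
}

with_seed <- cfrnadx:::with_seed

runif_det <- function(n, lo, hi, seed) with_seed(seed, runif(n, lo, hi))

# Null NB Wald run shared by calibration checks: 2,000 genes, 20 vs 20,
# phi = 0.1, unit size factors.
null_de <- function() cached_fixture("null_de", {
  mu <- exp(runif_det(2000, log(20), log(2000), seed = 51))
  counts <- nb_matrix(mu, 40, phi = 0.1, seed = 52)
  s <- stats::setNames(rep(1, 40), colnames(counts))
  nb_wald_test(counts, s,
               stats::setNames(rep(0.1, 2000), rownames(counts)),
               rep(c("A", "B"), each = 20))
})
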