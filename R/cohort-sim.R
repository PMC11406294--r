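#' Default cell-type panel for synthetic references
#'
#' Thirteen cell types: seven blood lineages that dominate plasma cfRNA, plus
#' the six solid-tissue types used for organ-injury reporting (endothelium,
#' heart, liver, lung x2, peripheral nerve).
#'
#' @return Character vector of cell-type labels.
#' @export
default_cell_types <- function() {
  c("neutrophil", "monocyte", "T cell", "B cell", "NK cell", "platelet",
    "erythrocyte", "endothelial cell", "cardiac muscle cell", "hepatocyte",
    "club cell", "type I pneumocyte", "Schwann cell")
}

#' Generate a synthetic cell-type reference signature matrix
#'
#' Each cell type shares a common baseline expression spectrum, perturbed by
#' lognormal noise, and receives a disjoint block of marker genes with
#' strongly elevated relative expression. Disjoint markers make the mixture
#' model identifiable by construction (the profile matrix has full row rank).
#'
#' @param n_cell_types Number of cell types (>= 2).
#' @param n_genes Number of genes (>= n_cell_types).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param cell_type_ids Optional character vector of labels; defaults to
#'   [default_cell_types()] when `n_cell_types` matches its length, otherwise
#'   `cell_type_1 ...`.
#' @param marker_fraction Fraction of genes reserved as markers per cell type.
#' @param marker_boost Multiplicative elevation of marker genes.
#' @return A `cfrna_reference` list with `cell_type_ids`, `gene_ids`,
#'   `profiles` (cell types x genes, rows summing to 1) and `marker_genes`.
#' @export
make_reference <- function(n_cell_types, n_genes, seed = 1L,
                           cell_type_ids = NULL,
                           marker_fraction = 0.01, marker_boost = 25) {
  if (n_cell_types < 2) stop("n_cell_types must be >= 2")
  if (n_genes < n_cell_types) stop("n_genes must be >= n_cell_types")
  if (is.null(cell_type_ids)) {
    cell_type_ids <- if (n_cell_types == length(default_cell_types()))
      default_cell_types() else paste0("cell_type_", seq_len(n_cell_types))
  }
  if (length(cell_type_ids) != n_cell_types || anyDuplicated(cell_type_ids))
    stop("cell_type_ids must be ", n_cell_types, " unique labels")
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  n_marker <- max(3L, floor(n_genes * marker_fraction))
  if (n_marker * n_cell_types > n_genes)
    n_marker <- max(1L, n_genes %/% (2L * n_cell_types))

  with_seed(seed, {
    baseline <- rgamma(n_genes, shape = 0.6, rate = 1) + 1e-4
    profiles <- matrix(0, n_cell_types, n_genes,
                       dimnames = list(cell_type_ids, gene_ids))
    marker_genes <- vector("list", n_cell_types)
    names(marker_genes) <- cell_type_ids
    for (c_idx in seq_len(n_cell_types)) {
      expr <- baseline * exp(rnorm(n_genes, 0, 0.5))
      idx <- ((c_idx - 1L) * n_marker + 1L):(c_idx * n_marker)
      expr[idx] <- expr[idx] * marker_boost
      marker_genes[[c_idx]] <- gene_ids[idx]
      profiles[c_idx, ] <- expr / sum(expr)
    }
    structure(list(cell_type_ids = cell_type_ids, gene_ids = gene_ids,
                   profiles = profiles, marker_genes = marker_genes),
              class = "cfrna_reference")
  })
}

#' Build a simulation configuration
#'
#' Defaults emulate the study cohort: 370 plasma samples across six groups
#' (Kawasaki disease n = 101, MIS-C n = 97, viral, bacterial, healthy, other
#' hospitalized controls), overdispersed counts arising as Dirichlet mixtures
#' of cell-type profiles, per-group planted gene signatures plus a shared
#' "inflammation" signature common to all disease groups, library sizes well
#' above the 75,000-count QC floor except for planted QC failures.
#'
#' @param group_sizes Named integer vector of samples per group.
#' @param n_genes,n_cell_types Dimensions of the simulated count matrix.
#' @param dirichlet_alpha Named list, one concentration vector per group
#'   (length `n_cell_types`); `NULL` uses built-in group-specific defaults.
#' @param signature_size Planted differentially abundant genes per disease
#'   group (disjoint across groups).
#' @param shared_signature_size Genes of the shared inflammation signature
#'   planted in every disease group; 0 disables it.
#' @param signature_log2fc Mean planted log2 fold change; realized per-gene
#'   effects are drawn around this value (exactly 0 when it is 0).
#' @param dispersion_mean Scale of per-gene NB dispersion phi (variance
#'   mu + phi * mu^2); gene dispersions are lognormal around it.
#' @param dispersion_sdlog Lognormal sdlog of per-gene dispersions.
#' @param library_size_range Min/max of per-sample total counts (uniform).
#' @param qc_fail_fraction Fraction of samples planted to fail exactly one
#'   QC rule each.
#' @param covariate_params Parameters for [simulate_clinical_covariates()].
#' @param seed Integer seed.
#' @return A `cfrna_sim_config` list.
#' @export
simulation_config <- function(group_sizes = c("KD" = 101, "MIS-C" = 97,
                                              "viral" = 60, "bacterial" = 30,
                                              "healthy" = 50, "other" = 32),
                              n_genes = 5000, n_cell_types = 13,
                              dirichlet_alpha = NULL,
                              signature_size = 30,
                              shared_signature_size = 60,
                              signature_log2fc = 2,
                              dispersion_mean = 0.15,
                              dispersion_sdlog = 0.5,
                              library_size_range = c(1e5, 1e6),
                              qc_fail_fraction = 0.05,
                              covariate_params = default_covariate_params(),
                              seed = 1L) {
  if (is.null(names(group_sizes)) || anyDuplicated(names(group_sizes)))
    stop("group_sizes must be uniquely named")
  if (any(group_sizes < 0)) stop("group_sizes must be >= 0")
  if (signature_size > n_genes) stop("signature_size exceeds n_genes")
  if (library_size_range[1] <= 0) stop("library_size_range min must be > 0")
  if (qc_fail_fraction < 0 || qc_fail_fraction > 1)
    stop("qc_fail_fraction must lie in [0, 1]")
  cfg <- list(group_sizes = group_sizes, n_genes = n_genes,
              n_cell_types = n_cell_types,
              dirichlet_alpha = dirichlet_alpha,
              signature_size = signature_size,
              shared_signature_size = shared_signature_size,
              signature_log2fc = signature_log2fc,
              dispersion_mean = dispersion_mean,
              dispersion_sdlog = dispersion_sdlog,
              library_size_range = library_size_range,
              qc_fail_fraction = qc_fail_fraction,
              covariate_params = covariate_params,
              seed = seed)
  class(cfg) <- "cfrna_sim_config"
  cfg
}

#' @export
#' @rdname simulate_clinical_covariates
default_covariate_params <- function() {
  list(alt_intercept = 15, alt_slope = 800, alt_sd = 8,
       cardiac_quantile = 0.75, cardiac_mislabel_rate = 0.02,
       severity_noise_sd = 0.005)
}

# Built-in Dirichlet concentrations: blood lineages dominate; disease groups
# shift solid-tissue fractions (cardiac/endothelial in KD and MIS-C, lung in
# viral, neutrophil expansion in bacterial).
default_dirichlet_alpha <- function(groups, cell_types) {
  base <- c("neutrophil" = 6, "monocyte" = 4, "T cell" = 4, "B cell" = 3,
            "NK cell" = 2, "platelet" = 2, "erythrocyte" = 2,
            "endothelial cell" = 0.8, "cardiac muscle cell" = 0.3,
            "hepatocyte" = 0.8, "club cell" = 0.5,
            "type I pneumocyte" = 0.5, "Schwann cell" = 0.3)
  if (!all(cell_types %in% names(base)))
    base <- stats::setNames(rep(2, length(cell_types)), cell_types)
  alpha <- lapply(groups, function(g) {
    a <- base[cell_types]
    switch(g,
           "KD" = { a["cardiac muscle cell"] <- 0.9; a["endothelial cell"] <- 1.6 },
           "MIS-C" = { a["cardiac muscle cell"] <- 1.2; a["endothelial cell"] <- 1.6
                       a["hepatocyte"] <- 1.2 },
           "viral" = { a["club cell"] <- 1.4; a["type I pneumocyte"] <- 1.4
                       a["hepatocyte"] <- 1.0 },
           "bacterial" = { a["neutrophil"] <- 9; a["hepatocyte"] <- 1.2 },
           "other" = { a["hepatocyte"] <- 1.0 },
           NULL)
    a
  })
  names(alpha) <- groups
  alpha
}

disease_groups <- function(groups) setdiff(groups, "healthy")

#' Simulate a synthetic cfRNA cohort with ground truth
#'
#' For each sample j in group g, cell-type fractions theta_j are drawn from a
#' group-specific Dirichlet; expected relative expression is the mixture
#' `t(profiles) %*% theta`, multiplied by `2^delta` on the group's planted
#' signature genes; counts are negative binomial with per-gene lognormal
#' dispersions and uniform library sizes. QC metrics are drawn from passing
#' ranges except for a planted fraction of samples that each fail exactly one
#' rule. Hospitals are assigned independently of counts (no batch effect).
#'
#' @param config A [simulation_config()].
#' @param reference A [make_reference()] result with `config$n_genes` genes.
#' @return A `cfrna_cohort` list: `counts` (genes x samples integer matrix),
#'   `metadata` (one row per sample: group, hospital, subgroup, QC metrics,
#'   ALT, cardiac_function, covid_severity, planted QC reason), `truth`
#'   (theta, planted signatures, realized log2 fold changes, dispersions,
#'   library sizes) and the `reference` used.
#' @export
simulate_cohort <- function(config, reference) {
  stopifnot(inherits(config, "cfrna_sim_config"),
            inherits(reference, "cfrna_reference"))
  if (length(reference$gene_ids) != config$n_genes)
    stop("reference gene count must equal config$n_genes")
  if (nrow(reference$profiles) != config$n_cell_types)
    stop("reference cell-type count must equal config$n_cell_types")

  groups <- names(config$group_sizes)
  alpha <- config$dirichlet_alpha %||%
    default_dirichlet_alpha(groups, reference$cell_type_ids)
  bad_len <- vapply(alpha, length, 1L) != config$n_cell_types
  if (any(bad_len))
    stop("dirichlet_alpha length mismatch for group(s): ",
         paste(names(alpha)[bad_len], collapse = ", "))

  n_total <- sum(config$group_sizes)
  group_vec <- rep(groups, config$group_sizes)
  sample_ids <- sprintf("S%04d", seq_len(n_total))
  gene_ids <- reference$gene_ids

  with_seed(config$seed, {
    ## planted signatures: disjoint per disease group, plus shared signature
    dgroups <- disease_groups(groups)
    n_sig <- config$signature_size
    n_shared <- config$shared_signature_size
    needed <- n_sig * length(dgroups) + n_shared
    if (needed > config$n_genes) stop("planted signatures exceed n_genes")
    pool <- sample(gene_ids, needed)
    signatures <- list()
    k <- 0L
    for (g in dgroups) {
      signatures[[g]] <- if (n_sig > 0) pool[(k + 1):(k + n_sig)] else character()
      k <- k + n_sig
    }
    shared_sig <- if (n_shared > 0) pool[(k + 1):(k + n_shared)] else character()

    lfc_sd <- 0.125 * config$signature_log2fc
    draw_delta <- function(n) stats::rnorm(n, config$signature_log2fc, lfc_sd)
    shared_delta <- stats::setNames(draw_delta(length(shared_sig)), shared_sig)
    realized_lfc <- lapply(dgroups, function(g) {
      own <- stats::setNames(draw_delta(length(signatures[[g]])), signatures[[g]])
      c(own, shared_delta)
    })
    names(realized_lfc) <- dgroups

    ## mixture fractions
    theta <- matrix(0, n_total, config$n_cell_types,
                    dimnames = list(sample_ids, reference$cell_type_ids))
    for (j in seq_len(n_total)) {
      a <- alpha[[group_vec[j]]]
      draw <- stats::rgamma(config$n_cell_types, shape = a, rate = 1)
      theta[j, ] <- draw / sum(draw)
    }

    ## library sizes and planted QC failures
    lib <- stats::runif(n_total, config$library_size_range[1],
                        config$library_size_range[2])
    n_fail <- round(config$qc_fail_fraction * n_total)
    fail_idx <- if (n_fail > 0) sample(n_total, n_fail) else integer()
    fail_rule <- rep_len(c("intron_exon", "total_counts", "bias_5to3"),
                         n_fail)
    lib[fail_idx[fail_rule == "total_counts"]] <-
      stats::runif(sum(fail_rule == "total_counts"), 3e4, 6e4)

    ## per-gene dispersions
    phi <- stats::rlnorm(config$n_genes, log(config$dispersion_mean),
                         config$dispersion_sdlog)
    names(phi) <- gene_ids

    ## counts
    counts <- matrix(0L, config$n_genes, n_total,
                     dimnames = list(gene_ids, sample_ids))
    eff <- matrix(0, config$n_genes, length(groups),
                  dimnames = list(gene_ids, groups))
    for (g in dgroups) eff[names(realized_lfc[[g]]), g] <- realized_lfc[[g]]
    for (j in seq_len(n_total)) {
      x <- as.vector(crossprod(reference$profiles, theta[j, ]))
      x <- x * 2^eff[, group_vec[j]]
      mu <- lib[j] * x / sum(x)
      counts[, j] <- stats::rnbinom(config$n_genes, mu = mu, size = 1 / phi)
    }

    ## QC metrics: passing draws, then overwrite planted failures
    ratio <- stats::runif(n_total, 0.5, 2.5)
    bias <- stats::runif(n_total, 0.8, 1.8)
    ratio[fail_idx[fail_rule == "intron_exon"]] <-
      stats::runif(sum(fail_rule == "intron_exon"), 3.2, 5)
    bias[fail_idx[fail_rule == "bias_5to3"]] <-
      stats::runif(sum(fail_rule == "bias_5to3"), 2.2, 3)
    planted_fail <- rep("", n_total)
    planted_fail[fail_idx] <- fail_rule

    metadata <- data.frame(
      sample_id = sample_ids,
      group = group_vec,
      hospital = sample(c("UCSD", "UCSF", "CNH", "Emory"), n_total,
                        replace = TRUE),
      subgroup = sample(c("subgroup_1", "subgroup_2"), n_total,
                        replace = TRUE),
      intron_exon_ratio = ratio,
      total_counts = colSums(counts),
      bias_5to3 = bias,
      qc_planted_fail = planted_fail,
      stringsAsFactors = FALSE
    )

    truth <- list(theta = theta, group = stats::setNames(group_vec, sample_ids),
                  signatures = signatures, shared_signature = shared_sig,
                  realized_log2fc = realized_lfc, dispersions = phi,
                  library_sizes = stats::setNames(lib, sample_ids))

    covars <- simulate_clinical_covariates(
      truth, config$covariate_params, child_seed(config$seed, 101))
    metadata <- cbind(metadata, covars[, c("ALT", "cardiac_function",
                                           "covid_severity")])

    structure(list(counts = counts, metadata = metadata, truth = truth,
                   reference = reference, config = config),
              class = "cfrna_cohort")
  })
}

#' Simulate clinical covariates tied to cell-type fractions
#'
#' ALT (IU/L) increases linearly with the hepatocyte fraction; the cardiac
#' function flag marks samples whose cardiac-muscle fraction exceeds an upper
#' quantile (with an optional mislabel rate); COVID severity (moderate /
#' severe, viral-group samples only) follows the summed lung fraction (club
#' cell + type I pneumocyte) with additive noise.
#'
#' @param truth List with `theta` (samples x cell types, columns must include
#'   hepatocyte, cardiac muscle cell, club cell, type I pneumocyte) and
#'   optionally `group` (severity is only assigned to the viral group).
#' @param params See [default_covariate_params()]: `alt_intercept`,
#'   `alt_slope`, `alt_sd`, `cardiac_quantile`, `cardiac_mislabel_rate`,
#'   `severity_noise_sd`.
#' @param seed Integer seed.
#' @return data.frame with `sample_id`, `ALT`, `cardiac_function`
#'   (normal/abnormal), `covid_severity` (moderate/severe/NA).
#' @export
simulate_clinical_covariates <- function(truth, params = default_covariate_params(),
                                         seed = 1L) {
  theta <- truth$theta
  need <- c("hepatocyte", "cardiac muscle cell", "club cell",
            "type I pneumocyte")
  missing <- setdiff(need, colnames(theta))
  if (length(missing))
    stop("theta is missing required cell type(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(theta)
  with_seed(seed, {
    alt <- params$alt_intercept + params$alt_slope * theta[, "hepatocyte"] +
      stats::rnorm(n, 0, params$alt_sd)
    alt <- pmax(alt, 1)

    thr <- stats::quantile(theta[, "cardiac muscle cell"],
                           params$cardiac_quantile, names = FALSE)
    abnormal <- theta[, "cardiac muscle cell"] > thr
    if (params$cardiac_mislabel_rate > 0) {
      flip <- stats::runif(n) < params$cardiac_mislabel_rate
      abnormal <- xor(abnormal, flip)
    }

    lung <- theta[, "club cell"] + theta[, "type I pneumocyte"] +
      stats::rnorm(n, 0, params$severity_noise_sd)
    severity <- rep(NA_character_, n)
    viral <- if (!is.null(truth$group)) truth$group == "viral" else rep(TRUE, n)
    if (any(viral)) {
      med <- stats::median(lung[viral])
      severity[viral] <- ifelse(lung[viral] > med, "severe", "moderate")
    }

    data.frame(sample_id = rownames(theta), ALT = alt,
               cardiac_function = ifelse(abnormal, "abnormal", "normal"),
               covid_severity = severity, stringsAsFactors = FALSE)
  })
}

#' @export
print.cfrna_cohort <- function(x, ...) {
  cat("Synthetic cfRNA cohort:", ncol(x$counts), "samples x",
      nrow(x$counts), "genes\n")
  print(table(x$metadata$group))
  invisible(x)
}
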