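#' Named filter presets for gene-panel selection
#'
#' `misc_kd`: adjusted p < 0.01, base mean > 100, two-sided gene AUC > 0.65,
#' |log2FC| > 0.25 (the binary KD vs MIS-C cascade). `multiclass_pairwise`:
#' adjusted p < 0.05, base mean > 50, |log2FC| > 1, top 150 by AUC (one panel
#' per one-vs-one pair). `covid_vs_other_viral`: the misc_kd thresholds plus
#' top 150 by AUC.
#'
#' @param name Preset name.
#' @return A filter-criteria list usable with [select_panel()].
#' @export
panel_preset <- function(name = c("misc_kd", "multiclass_pairwise",
                                  "covid_vs_other_viral")) {
  name <- match.arg(name)
  switch(name,
    misc_kd = list(q_max = 0.01, base_mean_min = 100, auc_min = 0.65,
                   abs_lfc_min = 0.25, top_n = NULL),
    multiclass_pairwise = list(q_max = 0.05, base_mean_min = 50,
                               auc_min = NULL, abs_lfc_min = 1, top_n = 150),
    covid_vs_other_viral = list(q_max = 0.01, base_mean_min = 100,
                                auc_min = 0.65, abs_lfc_min = 0.25,
                                top_n = 150))
}

#' Select a gene panel from a differential-abundance result
#'
#' Applies the filter cascade: q < q_max, base mean > base_mean_min,
#' two-sided AUC `max(auc, 1 - auc) > auc_min` (skipped when `auc_min` is
#' NULL), |log2FC| > abs_lfc_min. All comparisons strict. When `top_n` is
#' set, survivors are ordered by two-sided AUC descending (ties broken by
#' ascending q, then gene id) and truncated. The AUC filter is two-sided so
#' that strong markers of either group are retained.
#'
#' @param de_result data.frame from [run_de()] (needs `gene`, `q_value`,
#'   `base_mean`, `log2fc`, `gene_auc`).
#' @param criteria A [panel_preset()] or a list with the same fields.
#' @param name Panel name recorded in provenance.
#' @return A `cfrna_panel` list: `name`, `gene_ids` (ordered), `provenance`.
#' @export
select_panel <- function(de_result, criteria, name = "panel") {
  need <- c("gene", "q_value", "base_mean", "log2fc", "gene_auc")
  miss <- setdiff(need, names(de_result))
  if (length(miss)) stop("de_result missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- de_result[stats::complete.cases(de_result[, need]), ]
  steps <- list(
    q_value = function(d) d[d$q_value < criteria$q_max, ],
    base_mean = function(d) d[d$base_mean > criteria$base_mean_min, ],
    gene_auc = function(d) {
      if (is.null(criteria$auc_min)) d
      else d[pmax(d$gene_auc, 1 - d$gene_auc) > criteria$auc_min, ]
    },
    log2fc = function(d) d[abs(d$log2fc) > criteria$abs_lfc_min, ])
  for (step in names(steps)) {
    d <- steps[[step]](d)
    if (nrow(d) == 0)
      stop("no genes survive the filter cascade; first emptying filter: ",
           step)
  }
  auc2 <- pmax(d$gene_auc, 1 - d$gene_auc)
  ord <- order(-auc2, d$q_value, d$gene)
  d <- d[ord, ]
  if (!is.null(criteria$top_n))
    d <- utils::head(d, criteria$top_n)
  structure(list(name = name, gene_ids = d$gene,
                 provenance = list(criteria = criteria,
                                   n_input = nrow(de_result))),
            class = "cfrna_panel")
}

#' @export
print.cfrna_panel <- function(x, ...) {
  cat("Gene panel '", x$name, "': ", length(x$gene_ids), " genes\n", sep = "")
  invisible(x)
}

#' Serialize / restore a gene panel as JSON
#' @param panel A `cfrna_panel`.
#' @param path File path.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(list(name = panel$name, gene_ids = panel$gene_ids,
                            provenance = panel$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
#' @rdname write_panel
read_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(name = obj$name, gene_ids = obj$gene_ids,
                 provenance = obj$provenance), class = "cfrna_panel")
}
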