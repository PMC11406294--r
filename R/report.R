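#' Default organ to cell-type mapping for injury reporting
#'
#' Endothelium = endothelial cell; heart = cardiac muscle cell; liver =
#' hepatocyte; lung = club cell + type I pneumocyte; neuronal = Schwann cell.
#'
#' @return Named list organ -> character vector of cell types.
#' @export
default_organ_map <- function() {
  list(endothelium = "endothelial cell",
       heart = "cardiac muscle cell",
       liver = "hepatocyte",
       lung = c("club cell", "type I pneumocyte"),
       neuronal = "Schwann cell")
}

#' Healthy-donor organ fraction statistics
#'
#' Per organ, the mean and sd (n-1 denominator) of the summed mapped
#' cell-type fractions over healthy samples. Organs with zero spread get an
#' sd floor of 1e-8 and are flagged, so downstream z-scores carry a
#' low-confidence flag instead of dividing by zero.
#'
#' @param fractions Samples x cell types matrix (unscaled fractions).
#' @param healthy_ids Sample ids of healthy donors (>= 2).
#' @param organ_map From [default_organ_map()].
#' @return A `cfrna_healthy_stats` list: per-organ `mean`, `sd`, `floored`,
#'   plus `n_healthy` and the organ map.
#' @export
healthy_stats <- function(fractions, healthy_ids,
                          organ_map = default_organ_map()) {
  if (length(healthy_ids) < 2) stop("need >= 2 healthy samples")
  miss <- setdiff(healthy_ids, rownames(fractions))
  if (length(miss)) stop("healthy sample(s) absent from fractions: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  organ_fr <- organ_fractions(fractions[healthy_ids, , drop = FALSE],
                              organ_map)
  mu <- colMeans(organ_fr)
  sd <- apply(organ_fr, 2, stats::sd)
  floored <- sd < 1e-8
  sd[floored] <- 1e-8
  structure(list(mean = mu, sd = sd, floored = floored,
                 n_healthy = length(healthy_ids), organ_map = organ_map),
            class = "cfrna_healthy_stats")
}

# Samples x organs matrix of summed mapped cell-type fractions.
organ_fractions <- function(fractions, organ_map) {
  out <- vapply(names(organ_map), function(org) {
    cts <- organ_map[[org]]
    miss <- setdiff(cts, colnames(fractions))
    if (length(miss)) stop("organ '", org, "' maps to cell type(s) absent ",
                           "from fractions: ", paste(miss, collapse = ", "))
    rowSums(fractions[, cts, drop = FALSE])
  }, numeric(nrow(fractions)))
  if (nrow(fractions) == 1)
    out <- matrix(out, nrow = 1, dimnames = list(rownames(fractions),
                                                 names(organ_map)))
  out
}

#' Organ-injury z-scores relative to healthy donors
#'
#' `z = (organ fraction - healthy mean) / healthy sd`, computed on unscaled
#' fractions (z-scoring is itself the standardization; cohort min-max
#' scaling is only used for group-comparison plots). Organs whose healthy sd
#' was floored are flagged low-confidence.
#'
#' @param sample_fractions Samples x cell types matrix (or one row).
#' @param stats A [healthy_stats()] object.
#' @return Samples x organs matrix of z-scores, with attribute
#'   `"low_confidence"` naming floored organs.
#' @export
organ_zscores <- function(sample_fractions, stats) {
  stopifnot(inherits(stats, "cfrna_healthy_stats"))
  of <- organ_fractions(sample_fractions, stats$organ_map)
  z <- sweep(sweep(of, 2, stats$mean, "-"), 2, stats$sd, "/")
  attr(z, "low_confidence") <- names(stats$mean)[stats$floored]
  z
}

#' Assemble a per-patient diagnostic report
#'
#' Combines the multiclass probability vector (diagnoses ranked by
#' descending probability, with a borderline flag when the top two differ by
#' less than `margin`), organ-injury z-scores, QC status, and optionally the
#' binary KD-vs-MIS-C score with its Youden call.
#'
#' @param sample_id Sample identifier.
#' @param class_probs Named numeric probability vector (sums to 1).
#' @param zscores Named per-organ z-scores for this sample.
#' @param qc_status "pass" or "fail".
#' @param binary Optional list(score, call, threshold) from the binary path.
#' @param margin Borderline margin on the top-two probability gap.
#' @param model_version Identifier string recorded in the report.
#' @return A `cfrna_report` list.
#' @export
build_report <- function(sample_id, class_probs, zscores, qc_status = "pass",
                         binary = NULL, margin = 0.10,
                         model_version = "cfrnadx-0.1.0") {
  if (abs(sum(class_probs) - 1) > 1e-6)
    stop("class probabilities must sum to 1 (got ", sum(class_probs), ")")
  ord <- order(-class_probs, names(class_probs))
  ranked <- names(class_probs)[ord]
  gap <- class_probs[ord[1]] - class_probs[ord[2]]
  structure(list(sample_id = sample_id,
                 schema_version = "1",
                 model_version = model_version,
                 class_probabilities = as.list(class_probs),
                 ranked_diagnoses = ranked,
                 predicted = ranked[1],
                 borderline = unname(gap < margin),
                 borderline_margin = margin,
                 binary = binary,
                 organ_zscores = as.list(zscores),
                 low_confidence_organs =
                   as.character(attr(zscores, "low_confidence") %||% character()),
                 qc_status = qc_status),
            class = "cfrna_report")
}

#' Serialize a patient report to JSON and back
#'
#' The JSON rendering is lossless for all numeric fields (full double
#' precision); `report_from_json(report_to_json(x))` reproduces the report.
#'
#' @param report A `cfrna_report`.
#' @param path Optional file path; when NULL the JSON string is returned.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- unclass(report)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
#' @rdname report_to_json
report_from_json <- function(json) {
  obj <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = FALSE)
         else jsonlite::fromJSON(json, simplifyVector = FALSE)
  obj$class_probabilities <- unlist(obj$class_probabilities)
  obj$organ_zscores <- unlist(obj$organ_zscores)
  obj$ranked_diagnoses <- as.character(unlist(obj$ranked_diagnoses))
  obj$low_confidence_organs <- as.character(unlist(obj$low_confidence_organs))
  if (!is.null(obj$binary)) obj$binary <- lapply(obj$binary, unlist)
  structure(obj, class = "cfrna_report")
}

#' Render a patient report as markdown
#'
#' Numbers are printed at full double precision so the rendering is lossless.
#'
#' @param report A `cfrna_report`.
#' @return Character scalar of markdown.
#' @export
report_to_markdown <- function(report) {
  num <- function(x) format(x, digits = 17, trim = TRUE)
  p <- unlist(report$class_probabilities)
  lines <- c(
    sprintf("# Diagnostic report: %s", report$sample_id),
    "",
    sprintf("- QC status: %s", report$qc_status),
    sprintf("- Predicted condition: **%s**%s", report$predicted,
            if (isTRUE(report$borderline)) " (borderline)" else ""),
    "",
    "## Class probabilities", "",
    sprintf("- %s: %s", report$ranked_diagnoses,
            num(p[report$ranked_diagnoses])),
    "",
    "## Organ injury z-scores (vs healthy donors)", "",
    sprintf("- %s: %s%s", names(report$organ_zscores),
            num(unlist(report$organ_zscores)),
            ifelse(names(report$organ_zscores) %in%
                     report$low_confidence_organs, " (low confidence)", "")))
  if (!is.null(report$binary))
    lines <- c(lines, "", "## Binary KD vs MIS-C", "",
               sprintf("- score: %s (threshold %s) -> %s",
                       num(report$binary$score), num(report$binary$threshold),
                       report$binary$call))
  paste(lines, collapse = "\n")
}

#' @export
print.cfrna_report <- function(x, ...) {
  cat(report_to_markdown(x), "\n")
  invisible(x)
}
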