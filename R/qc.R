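#' Default sample quality-control thresholds
#'
#' Samples are removed when the intron-to-exon read ratio exceeds 3 (DNA
#' contamination), total feature counts fall below 75,000, or the 5'-3' read
#' alignment bias exceeds 2 (RNA degradation). All three rules are strict
#' inequalities: a sample sitting exactly on a boundary passes.
#'
#' @return List with `max_intron_exon`, `min_total_counts`, `max_bias`.
#' @export
qc_thresholds <- function(max_intron_exon = 3, min_total_counts = 75000,
                          max_bias = 2) {
  if (max_intron_exon <= 0 || min_total_counts <= 0 || max_bias <= 0)
    stop("QC thresholds must be positive")
  list(max_intron_exon = max_intron_exon,
       min_total_counts = min_total_counts,
       max_bias = max_bias)
}

#' Apply sample-level quality filters
#'
#' A sample fails iff `intron_exon_ratio > max_intron_exon` OR
#' `total_counts < min_total_counts` OR `bias_5to3 > max_bias`; boundary
#' values pass. Decisions are a pure function of the three metrics and the
#' thresholds; rRNA contamination, if recorded, is never used for filtering.
#'
#' @param metrics data.frame with columns `sample_id`, `intron_exon_ratio`,
#'   `total_counts`, `bias_5to3` (extra columns ignored).
#' @param thresholds A [qc_thresholds()] list.
#' @return data.frame with `sample_id`, `pass` (logical) and `reasons`
#'   (semicolon-joined names of every violated rule; "" when passing).
#' @export
apply_qc <- function(metrics, thresholds = qc_thresholds()) {
  need <- c("sample_id", "intron_exon_ratio", "total_counts", "bias_5to3")
  miss_col <- setdiff(need, names(metrics))
  if (length(miss_col))
    stop("metrics table is missing column(s): ", paste(miss_col, collapse = ", "))
  for (col in need[-1]) {
    bad <- !is.finite(metrics[[col]])
    if (any(bad))
      stop(sprintf("missing or non-finite QC metric '%s' for sample '%s'",
                   col, metrics$sample_id[which(bad)[1]]))
  }
  fail_ie <- metrics$intron_exon_ratio > thresholds$max_intron_exon
  fail_tc <- metrics$total_counts < thresholds$min_total_counts
  fail_bias <- metrics$bias_5to3 > thresholds$max_bias
  reasons <- mapply(function(a, b, c) {
    paste(c("intron_exon", "total_counts", "bias_5to3")[c(a, b, c)],
          collapse = ";")
  }, fail_ie, fail_tc, fail_bias)
  data.frame(sample_id = metrics$sample_id,
             pass = !(fail_ie | fail_tc | fail_bias),
             reasons = unname(reasons), stringsAsFactors = FALSE)
}
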