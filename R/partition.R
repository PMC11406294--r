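#' Stratified train/validation/test partitioning
#'
#' Samples are allocated within each stratum cell (cross-product of the
#' strata keys) by seeded shuffling and largest-remainder rounding, so that
#' set sizes per cell are within one sample of the exact ratios. Cells with
#' fewer samples than there are sets are collapsed to their group-only cell
#' (with a warning) before allocation.
#'
#' @param metadata data.frame with `sample_id` and the strata columns.
#' @param ratios Named numeric vector summing to 100, e.g.
#'   `c(train = 60, validation = 20, test = 20)` or `c(train = 70, test = 30)`.
#' @param strata Character vector of metadata columns to stratify on.
#' @param seed Integer seed.
#' @return Named character vector: set assignment per sample_id.
#' @export
stratified_partition <- function(metadata, ratios, strata = c("group"),
                                 seed = 1L) {
  if (abs(sum(ratios) - 100) > 1e-8) stop("ratios must sum to 100")
  if (is.null(names(ratios))) stop("ratios must be named")
  miss <- setdiff(strata, names(metadata))
  if (length(miss)) stop("strata key(s) not in metadata: ",
                         paste(miss, collapse = ", "))
  n_sets <- length(ratios)
  cell <- do.call(paste, c(metadata[strata], sep = "\r"))
  small <- names(which(table(cell) < n_sets))
  if (length(small)) {
    warning(length(small), " stratum cell(s) smaller than the number of ",
            "sets; collapsed to group-only strata")
    fallback <- if ("group" %in% names(metadata))
      metadata$group else rep("all", nrow(metadata))
    cell[cell %in% small] <- paste0("collapsed\r", fallback[cell %in% small])
  }
  assignment <- character(nrow(metadata))
  with_seed(seed, {
    for (cl in unique(cell)) {
      idx <- which(cell == cl)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      quota <- n * ratios / 100
      base <- floor(quota)
      leftover <- n - sum(base)
      if (leftover > 0) {
        extra <- order(-(quota - base), seq_along(ratios))[seq_len(leftover)]
        base[extra] <- base[extra] + 1
      }
      assignment[idx] <- rep(names(ratios), base)
    }
  })
  stats::setNames(assignment, metadata$sample_id)
}
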