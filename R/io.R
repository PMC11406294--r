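# Plain-text I/O for cohorts and count matrices.

#' Write / read a gene x sample count matrix as TSV
#'
#' First column `gene_id`, one column per sample.
#'
#' @param counts Gene x sample matrix.
#' @param path File path.
#' @export
write_counts_tsv <- function(counts, path) {
  assert_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname write_counts_tsv
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  assert_count_matrix(m)
}

#' Write a synthetic cohort to a directory
#'
#' Counts as TSV, metadata and true mixture fractions as CSV.
#'
#' @param cohort A `cfrna_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  theta <- data.frame(sample_id = rownames(cohort$truth$theta),
                      cohort$truth$theta, check.names = FALSE)
  utils::write.csv(theta, file.path(dir, "truth_fractions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
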