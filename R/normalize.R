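# Normalization utilities presupposed by the permutation test: log2
# transform, quantile normalization, and mean probeset-to-gene
# summarization.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share a common distribution: the sorted
#' values of each column are replaced by the across-sample mean of sorted
#' values at each rank; tied values within a column receive the mean of
#' their rank means. Delegates to [limma::normalizeQuantiles()].
#'
#' @param mat numeric gene x sample matrix with >= 2 columns.
#' @return matrix of the same dimension with identical column
#'   distributions.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("quantile normalization needs >= 2 samples",
                          call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Elementwise log2 transform
#'
#' @param mat numeric matrix of non-negative expression values.
#' @param offset pseudo-value added before the log (default 0); every
#'   `value + offset` must be positive.
#' @return `log2(mat + offset)`.
#' @export
log2_transform <- function(mat, offset = 0) {
  mat <- as.matrix(mat)
  bad <- which(rowSums(mat + offset <= 0) > 0)
  if (length(bad)) {
    nm <- if (!is.null(rownames(mat))) rownames(mat)[bad] else as.character(bad)
    stop(sprintf("log2 undefined (value + offset <= 0) for %d gene(s): %s",
                 length(bad),
                 paste(utils::head(nm, 5), collapse = ", ")), call. = FALSE)
  }
  log2(mat + offset)
}

#' Mean-summarize probes to genes
#'
#' Per gene and sample, the mean of the mapped probes' values. Probes
#' absent from the map are dropped with a message.
#'
#' @param mat numeric probe x sample matrix with probe rownames.
#' @param probe_map data frame with columns `probe_id` and `gene_id`.
#' @return numeric gene x sample matrix.
#' @export
summarize_probesets <- function(mat, probe_map) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("`mat` needs probe rownames", call. = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(probe_map)) ||
      nrow(probe_map) == 0) {
    stop("`probe_map` must be a non-empty data frame with probe_id and gene_id",
         call. = FALSE)
  }
  gene <- probe_map$gene_id[match(rownames(mat), probe_map$probe_id)]
  unmapped <- is.na(gene)
  if (all(unmapped)) stop("no probe of `mat` is present in `probe_map`",
                          call. = FALSE)
  if (any(unmapped)) {
    message(sum(unmapped), " unmapped probe(s) dropped")
  }
  m <- mat[!unmapped, , drop = FALSE]
  g <- gene[!unmapped]
  sums <- rowsum(m, group = g)
  sums / as.vector(table(g)[rownames(sums)])
}
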