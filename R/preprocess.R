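# Expression preprocessing: log-CPM, low-expression filtering, cyclic loess
# normalization, row z-scoring.

#' Log2 counts-per-million transform
#'
#' `log2((count + offset) / (library_size + 2 * offset) * 1e6)`, the usual
#' pseudo-counted CPM on the log2 scale. Library sizes are the column sums
#' of the raw counts.
#'
#' @param counts non-negative raw count matrix, genes x samples.
#' @param offset pseudo-count added to each count (default 0.5).
#' @return log2-CPM matrix of the same shape.
#' @export
log_cpm <- function(counts, offset = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_named("log_cpm expects non-negative raw counts")
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero)) {
    stop_named("zero library size for sample(s): %s",
               paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  }
  log2(sweep(counts + offset, 2, lib + 2 * offset, "/") * 1e6)
}

#' Remove unexpressed and lowly expressed genes
#'
#' Drops genes with zero reads in every sample, then genes with fewer than
#' 1 read per million in strictly more than 50% of samples (a gene needing
#' CPM >= 1 in at least half the samples to be kept). Gene order is
#' preserved.
#'
#' @param counts raw count matrix, genes x samples.
#' @param cpm_cut CPM threshold (default 1).
#' @param max_low_fraction genes with CPM below `cpm_cut` in strictly more
#'   than this fraction of samples are removed (default 0.5).
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, cpm_cut = 1, max_low_fraction = 0.5) {
  counts <- as.matrix(counts)
  keep0 <- rowSums(counts) > 0
  lib <- colSums(counts)
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  low_frac <- rowMeans(cpm < cpm_cut)
  keep <- keep0 & (low_frac <= max_low_fraction)
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no genes left after low-expression filtering")
  out
}

#' Cyclic loess normalization of log2 expression
#'
#' For every unordered sample pair an MA-trend loess smooth is estimated and
#' subtracted half from each sample, cycling over all pairs `n_cycles`
#' times (limma's pairwise cyclic loess). Per-pair average intensities (A)
#' are preserved.
#'
#' @param logexpr log2 expression matrix, genes x samples.
#' @param span loess span (default 0.7).
#' @param n_cycles number of passes over all pairs (default 3).
#' @return the normalized matrix.
#' @export
cyclic_loess_normalize <- function(logexpr, span = 0.7, n_cycles = 3) {
  logexpr <- as.matrix(logexpr)
  if (ncol(logexpr) < 2) {
    warning("fewer than 2 samples: cyclic loess is the identity")
    return(logexpr)
  }
  out <- limma::normalizeCyclicLoess(logexpr, span = span,
                                     iterations = n_cycles, method = "pairs")
  dimnames(out) <- dimnames(logexpr)
  out
}

#' Z-score the rows of an expression matrix
#'
#' Centers every gene to mean 0 and scales to unit standard deviation
#' (denominator n - 1), the usual heatmap scaling. Constant rows are mapped
#' to all zeros and flagged in the `"constant"` attribute.
#'
#' @param logexpr matrix with at least 2 columns.
#' @return the row-scaled matrix, with a logical `"constant"` attribute.
#' @export
zscore_rows <- function(logexpr) {
  logexpr <- as.matrix(logexpr)
  if (ncol(logexpr) < 2) stop_named("zscore_rows needs at least 2 samples")
  mu <- rowMeans(logexpr)
  centered <- logexpr - mu
  s <- sqrt(rowSums(centered^2) / (ncol(logexpr) - 1))
  const <- s == 0
  s[const] <- 1
  out <- centered / s
  out[const, ] <- 0
  attr(out, "constant") <- const
  out
}
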