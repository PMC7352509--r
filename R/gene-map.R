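#' Build the chromosomally ordered synthetic gene map
#'
#' Lays `n_genes` out evenly over `n_chromosomes` chromosomes (`chr1..chrN`;
#' chromosome sizes differ by at most one gene, earlier chromosomes take the
#' remainder). Within a chromosome, gene `j` occupies the 0-based half-open
#' interval `[(j-1)*1000, (j-1)*1000 + 500)`, so coordinates are strictly
#' increasing and non-overlapping. The `order` column is the total
#' chromosomal order used as the HMM emission order.
#'
#' @param spec a [cohort_spec()], or an integer `n_genes` when
#'   `n_chromosomes` is also given.
#' @param n_chromosomes number of chromosomes (only when `spec` is numeric).
#' @return a data frame of class `gene_map` with columns `gene`, `chrom`,
#'   `start`, `end`, `order`, and a `chrom_lengths` attribute.
#' @export
build_gene_map <- function(spec, n_chromosomes = NULL) {
  if (inherits(spec, "cohort_spec")) {
    validate_cohort_spec(spec)
    n_genes <- spec$n_genes
    n_chrom <- spec$n_chromosomes
  } else {
    n_genes <- as.integer(spec)
    n_chrom <- as.integer(n_chromosomes)
  }
  if (n_genes < n_chrom) {
    stop_named("invalid spec: n_genes (%d) < n_chromosomes (%d)", n_genes, n_chrom)
  }
  sizes <- rep(n_genes %/% n_chrom, n_chrom)
  extra <- n_genes %% n_chrom
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  chrom <- rep(paste0("chr", seq_len(n_chrom)), sizes)
  within <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  gm <- data.frame(
    gene = sprintf("g%05d", seq_len(n_genes)),
    chrom = chrom,
    start = (within - 1L) * 1000,
    end = (within - 1L) * 1000 + 500,
    order = seq_len(n_genes),
    stringsAsFactors = FALSE
  )
  attr(gm, "chrom_lengths") <- setNames(sizes * 1000, paste0("chr", seq_len(n_chrom)))
  class(gm) <- c("gene_map", "data.frame")
  gm
}

chrom_boundaries <- function(gene_map) {
  # run-length chunks of the gene order, one per chromosome
  r <- rle(gene_map$chrom)
  ends <- cumsum(r$lengths)
  data.frame(chrom = r$values, first = c(1L, head(ends, -1) + 1L), last = ends,
             stringsAsFactors = FALSE)
}
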