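# Copy-number: SEG io, segment-to-gene mapping, subgroup average profiles,
# chromosome/arm event calls.
#
# Internal coordinates are 0-based half-open everywhere; SEG files on disk
# are 1-based inclusive and converted at the boundary.

#' Read a SEG-style segment table
#'
#' Expects tab-separated columns `sample`, `chrom`, `start`, `end`,
#' `seg_mean` with 1-based inclusive coordinates, converted on ingest to the
#' package's 0-based half-open convention.
#'
#' @param path SEG TSV file.
#' @return data frame with 0-based half-open `start`/`end`.
#' @export
read_seg <- function(path) {
  seg <- read_tsv(path)
  names(seg) <- tolower(names(seg))
  need <- c("sample", "chrom", "start", "end", "seg_mean")
  if (!all(need %in% names(seg))) {
    stop_named("SEG file must have columns %s", paste(need, collapse = ", "))
  }
  seg$start <- seg$start - 1
  seg[, need]
}

#' Write segments as a SEG-style table (1-based inclusive on disk)
#'
#' @param seg segment data frame in internal 0-based half-open coordinates.
#' @param path output file.
#' @export
write_seg <- function(seg, path) {
  out <- seg
  out$start <- out$start + 1
  write_tsv(out, path)
}

#' Map copy-number segments to gene-level log2-ratio profiles
#'
#' Each gene receives the mean log2-ratio of the segment containing its
#' midpoint; genes whose midpoint falls in no segment (or whose chromosome
#' carries no segments for a sample) are `NA`.
#'
#' @param segs segment data frame (`sample`, `chrom`, `start`, `end`,
#'   `seg_mean`; 0-based half-open, non-overlapping within sample and
#'   chromosome).
#' @param genes a [build_gene_map()] result (or data frame with `gene`,
#'   `chrom`, `start`, `end`).
#' @return matrix genes x samples of per-gene log2-ratios, rows in gene-map
#'   order.
#' @export
segments_to_genes <- function(segs, genes) {
  samples <- unique(segs$sample)
  mid <- (genes$start + genes$end) / 2
  out <- matrix(NA_real_, nrow(genes), length(samples),
                dimnames = list(genes$gene, samples))
  for (smp in samples) {
    ss <- segs[segs$sample == smp, , drop = FALSE]
    for (chrom in unique(ss$chrom)) {
      sc <- ss[ss$chrom == chrom, , drop = FALSE]
      sc <- sc[order(sc$start), , drop = FALSE]
      if (any(sc$start[-1] < sc$end[-nrow(sc)])) {
        stop_named("overlapping segments for sample %s on %s", smp, chrom)
      }
      gi <- which(genes$chrom == chrom)
      if (!length(gi)) next
      slot <- findInterval(mid[gi], sc$start)
      hit <- slot >= 1 & mid[gi] < sc$end[pmax(slot, 1)]
      out[gi[hit], smp] <- sc$seg_mean[slot[hit]]
    }
  }
  out
}

#' Average per-gene copy-number profile across samples
#'
#' @param profiles matrix genes x samples (or list of per-gene vectors);
#'   missing values are excluded per gene.
#' @return per-gene mean log2-ratio vector; genes missing in every profile
#'   stay `NA`.
#' @export
average_profile <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    profiles <- do.call(cbind, profiles)
  }
  profiles <- as.matrix(profiles)
  out <- rowMeans(profiles, na.rm = TRUE)
  out[rowSums(!is.na(profiles)) == 0] <- NA_real_
  out
}

#' Call a loss/gain/neutral event for one scope of genes
#'
#' A scope (whole chromosome or arm) is called `loss` when at least
#' `min_fraction` of its genes have log2-ratio at or below `loss_cut`,
#' `gain` symmetrically at or above `gain_cut`, and `neutral` otherwise.
#' When both directions qualify the larger fraction wins; equal fractions
#' give `neutral`.
#'
#' @param values per-gene log2-ratios of the scope (NAs dropped).
#' @param loss_cut,gain_cut log2-ratio cutoffs (defaults -0.3 / 0.3).
#' @param min_fraction minimum fraction of scope genes beyond the cutoff
#'   (default 0.7).
#' @return one of `"loss"`, `"gain"`, `"neutral"`.
#' @export
chromosome_event_call <- function(values, loss_cut = -0.3, gain_cut = 0.3,
                                  min_fraction = 0.7) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_named("empty scope: no genes with copy-number values")
  f_loss <- mean(values <= loss_cut)
  f_gain <- mean(values >= gain_cut)
  loss_ok <- f_loss >= min_fraction
  gain_ok <- f_gain >= min_fraction
  if (loss_ok && gain_ok) {
    if (f_loss > f_gain) "loss" else if (f_gain > f_loss) "gain" else "neutral"
  } else if (loss_ok) "loss" else if (gain_ok) "gain" else "neutral"
}

#' Tabulate chromosome (or arm) event calls for every sample
#'
#' @param profiles gene-level log2-ratio matrix from [segments_to_genes()].
#' @param gene_map matching gene map.
#' @param scope `"chromosome"` or `"arm"` (arms split each chromosome at
#'   half its length; the synthetic genome has no centromeres).
#' @param ... thresholds passed to [chromosome_event_call()].
#' @return data frame `sample`, `scope`, `label`.
#' @export
call_chromosome_events <- function(profiles, gene_map,
                                   scope = c("chromosome", "arm"), ...) {
  scope <- match.arg(scope)
  lens <- attr(gene_map, "chrom_lengths")
  if (scope == "chromosome") {
    scopes <- split(seq_len(nrow(gene_map)), gene_map$chrom)
  } else {
    mid <- (gene_map$start + gene_map$end) / 2
    arm <- ifelse(mid < lens[gene_map$chrom] / 2, "p", "q")
    scopes <- split(seq_len(nrow(gene_map)), paste0(gene_map$chrom, arm))
  }
  res <- expand.grid(sample = colnames(profiles), scope = names(scopes),
                     stringsAsFactors = FALSE)
  res$label <- vapply(seq_len(nrow(res)), function(i) {
    chromosome_event_call(profiles[scopes[[res$scope[i]]], res$sample[i]], ...)
  }, character(1))
  res
}
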