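# Somatic variant summaries for patient-matched pairs: shared/private
# partitions, functional-class tallies, gene-level mutation frequencies.

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

check_variant_set <- function(v, label = "variant set") {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(v))) {
    stop_named("%s must have columns %s", label, paste(need, collapse = ", "))
  }
  k <- variant_key(v)
  if (anyDuplicated(k)) {
    stop_named("duplicate variant key(s) within %s: %s", label,
               paste(unique(k[duplicated(k)]), collapse = ", "))
  }
  invisible(k)
}

#' Shared and private somatic variant counts of a matched pair
#'
#' Variant identity is the `(chrom, pos, ref, alt)` key.
#'
#' @param initial,recurrent variant data frames of the two tumors.
#' @return named integer vector `shared`, `initial_private`,
#'   `recurrent_private`.
#' @export
shared_private <- function(initial, recurrent) {
  ki <- check_variant_set(initial, "initial tumor")
  kr <- check_variant_set(recurrent, "recurrent tumor")
  c(shared = length(intersect(ki, kr)),
    initial_private = length(setdiff(ki, kr)),
    recurrent_private = length(setdiff(kr, ki)))
}

#' Tally variant calls by functional class
#'
#' Known classes are nonsynonymous, synonymous, stop, intronic and other;
#' unknown labels are counted under `other` with a warning. The `exonic`
#' entry is the sum of nonsynonymous, stop and synonymous calls.
#'
#' @param calls variant data frame with a `class` column.
#' @return named integer vector of per-class counts plus `exonic`.
#' @export
functional_tally <- function(calls) {
  known <- c("nonsynonymous", "synonymous", "stop", "intronic", "other")
  cls <- as.character(calls$class)
  bad <- setdiff(unique(cls), known)
  if (length(bad)) {
    warning(sprintf("unknown functional class label(s) counted as other: %s",
                    paste(bad, collapse = ", ")))
    cls[cls %in% bad] <- "other"
  }
  tab <- table(factor(cls, levels = known))
  out <- setNames(as.integer(tab), known)
  c(out, exonic = unname(out["nonsynonymous"] + out["stop"] + out["synonymous"]))
}

#' Gene-level mutation frequency across matched pairs
#'
#' Under scope `any-sample` a pair counts as mutated in a gene when either
#' tumor carries at least one variant in it; under `shared-in-pair` the same
#' `(chrom, pos, ref, alt)` key must be present in both tumors. With
#' `groups`, frequencies are additionally stratified by progression group.
#'
#' @param pairs a `variant_pairs` object, or a named list of
#'   `list(initial =, recurrent =)` variant data frames keyed by patient.
#' @param scope `"any-sample"` or `"shared-in-pair"`.
#' @param groups optional named list: group label -> patient ids.
#' @return data frame `gene`, `n_mutated`, `n_pairs`, `frequency` (plus a
#'   `group` column when stratified), sorted by descending frequency then
#'   gene name.
#' @export
gene_frequency <- function(pairs, scope = c("any-sample", "shared-in-pair"),
                           groups = NULL) {
  scope <- match.arg(scope)
  if (inherits(pairs, "variant_pairs")) pairs <- pairs$pairs
  per_pair_genes <- lapply(pairs, function(p) {
    if (scope == "any-sample") {
      unique(c(p$initial$gene, p$recurrent$gene))
    } else {
      ki <- variant_key(p$initial)
      kr <- variant_key(p$recurrent)
      unique(p$initial$gene[ki %in% kr])
    }
  })
  tally <- function(ids) {
    gl <- per_pair_genes[ids]
    counts <- table(unlist(gl))
    if (!length(counts)) {
      return(data.frame(gene = character(0), n_mutated = integer(0),
                        n_pairs = integer(0), frequency = numeric(0),
                        stringsAsFactors = FALSE))
    }
    out <- data.frame(gene = names(counts), n_mutated = as.integer(counts),
                      n_pairs = length(ids),
                      frequency = as.integer(counts) / length(ids),
                      stringsAsFactors = FALSE)
    out[order(-out$frequency, out$gene), , drop = FALSE]
  }
  if (is.null(groups)) {
    out <- tally(names(per_pair_genes))
    rownames(out) <- NULL
    return(out)
  }
  res <- do.call(rbind, lapply(names(groups), function(g) {
    t <- tally(intersect(groups[[g]], names(per_pair_genes)))
    if (nrow(t)) t$group <- g
    t
  }))
  rownames(res) <- NULL
  res
}
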