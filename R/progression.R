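# Aggregation of per-pair HMM expression-state calls into progression-group
# alteration sets, the >= 50%-of-pairs rule, Venn comparisons, and average
# alteration / pathway profiles.

#' Build progression groups from a sample sheet
#'
#' @param samples a cohort sample sheet (columns `patient`, `group`).
#' @return named list: group label -> character vector of patient ids.
#' @export
progression_groups <- function(samples) {
  tum <- samples[!is.na(samples$group), c("patient", "group")]
  tum <- unique(tum)
  split(tum$patient, tum$group)
}

#' Per-gene under/over call counts within each progression group
#'
#' @param decoding a [posterior_decode()] result (or a genes x pairs label
#'   matrix coded -1/0/+1).
#' @param groups named list: group -> patient ids (all must be decoded).
#' @return list of class `alteration_summary`: per group, a data frame
#'   `gene`, `n_under`, `n_over`, `n_pairs`.
#' @export
group_alteration_counts <- function(decoding, groups) {
  labels <- if (inherits(decoding, "posterior_decoding")) decoding$labels else decoding
  out <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    if (!length(members)) stop_named("progression group %s has zero pairs", g)
    miss <- setdiff(members, colnames(labels))
    if (length(miss)) {
      stop_named("group %s: no decoding for pair(s) %s", g,
                 paste(miss, collapse = ", "))
    }
    m <- labels[, members, drop = FALSE]
    data.frame(gene = rownames(labels),
               n_under = rowSums(m == -1L),
               n_over = rowSums(m == 1L),
               n_pairs = length(members),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- names(groups)
  class(out) <- c("alteration_summary", class(out))
  out
}

#' Frequently altered gene sets per group and their cross-group Venn
#'
#' A gene enters a group's under (over) set when it is called under (over)
#' in at least `min_fraction` of the group's pairs — the boundary is
#' inclusive, so with the default 0.5 a gene altered in exactly half the
#' pairs is kept.
#'
#' @param summary an [group_alteration_counts()] result.
#' @param min_fraction minimum fraction of pairs, in (0, 1] (default 0.5).
#' @return list with `sets` (per group: `under`, `over` gene vectors),
#'   `venn` (per direction, region counts across groups), and
#'   `opposite` (counts of genes under in one group and over in another,
#'   for every ordered group pair).
#' @export
frequent_sets <- function(summary, min_fraction = 0.5) {
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    stop_named("min_fraction must be in (0, 1]")
  }
  sets <- lapply(summary, function(s) {
    list(under = s$gene[s$n_under / s$n_pairs >= min_fraction],
         over = s$gene[s$n_over / s$n_pairs >= min_fraction])
  })
  venn <- lapply(c(under = "under", over = "over"), function(dir) {
    venn_regions(lapply(sets, `[[`, dir))
  })
  gn <- names(sets)
  opposite <- list()
  for (a in gn) for (b in gn) {
    if (a != b) {
      opposite[[paste0(a, ".under+", b, ".over")]] <-
        length(intersect(sets[[a]]$under, sets[[b]]$over))
    }
  }
  list(sets = sets, venn = venn, opposite = unlist(opposite))
}

#' Average alteration profile of a progression group
#'
#' For each requested gene, the mean log2-ratio over exactly those pairs of
#' the group whose decoded label matches the direction; genes with no
#' contributing pair are omitted. Output stays in chromosomal order.
#'
#' @param profiles a `pair_profiles` object (log-ratio values).
#' @param decoding matching [posterior_decode()] result.
#' @param group character vector of patient ids in the group.
#' @param direction `"under"` or `"over"`.
#' @param genes genes to report (default: all genes with >= 1 contributing
#'   pair; pass a frequent set to reproduce a per-group alteration profile).
#' @return data frame `gene`, `n_pairs`, `mean_logratio`.
#' @export
average_alteration_profile <- function(profiles, decoding, group,
                                       direction = c("under", "over"),
                                       genes = NULL) {
  direction <- match.arg(direction)
  want <- if (direction == "under") -1L else 1L
  vals <- profiles$values[, group, drop = FALSE]
  labs <- decoding$labels[, group, drop = FALSE]
  hit <- labs == want
  n_pairs <- rowSums(hit)
  msum <- rowSums(vals * hit)
  keep <- n_pairs > 0
  if (!is.null(genes)) keep <- keep & rownames(vals) %in% genes
  data.frame(gene = rownames(vals)[keep],
             n_pairs = n_pairs[keep],
             mean_logratio = msum[keep] / n_pairs[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pathway alteration profile of progression-group frequent sets
#'
#' Per pathway and direction: the fraction of its (measured) genes inside
#' each group's frequent set, with a one-sided Fisher overrepresentation
#' test against the gene universe.
#'
#' @param freq a [frequent_sets()] result.
#' @param annot named list: pathway -> gene vector.
#' @param universe character vector of measured genes.
#' @return data frame `group`, `direction`, `pathway`, `n_pathway`,
#'   `n_altered`, `proportion`, `odds`, `p`.
#' @export
pathway_alteration_profile <- function(freq, annot, universe) {
  rows <- list()
  for (g in names(freq$sets)) {
    for (dir in c("under", "over")) {
      geneset <- freq$sets[[g]][[dir]]
      enr <- category_enrichment(geneset, universe, annot)
      enr$proportion <- ifelse(enr$n_category > 0,
                               enr$overlap / enr$n_category, NA_real_)
      rows[[paste(g, dir)]] <- data.frame(
        group = g, direction = dir, pathway = enr$category,
        n_pathway = enr$n_category, n_altered = enr$overlap,
        proportion = enr$proportion, odds = enr$odds, p = enr$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
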