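# Two-group moderated differential expression, BH-FDR, Venn comparisons,
# Fisher category enrichment.

#' Moderated two-group differential expression test
#'
#' Per-gene two-sample contrast with empirical-Bayes variance moderation:
#' the pooled residual variance `s^2` on `d = nA + nB - 2` df is shrunk
#' toward a prior `(d0, s0^2)`, fitted across genes by the method of
#' moments on `log s^2` (matching the scaled-F hierarchical model), giving
#' the posterior variance `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` and a
#' moderated t statistic on `d0 + d` df (normal reference when `d0` is
#' infinite). Two-sided p-values, BH q-values, and an under/over/unchanged
#' direction call at `q <= q_cut`.
#'
#' @param logexpr log2 expression matrix, genes x samples.
#' @param groupA,groupB disjoint character vectors of sample ids (each of
#'   size >= 2). The log fold change is `mean(A) - mean(B)`.
#' @param q_cut q-value threshold for the direction call (default 0.01).
#' @param d0 optionally fix the prior df instead of fitting it (Inf gives
#'   the pooled-variance z-like limit, 0 the ordinary t-test).
#' @return data frame of class `de_result`: `gene`, `logfc`, `t`, `p`, `q`,
#'   `direction`; attributes `d0` and `s0sq` hold the fitted prior.
#' @export
moderated_two_group_test <- function(logexpr, groupA, groupB, q_cut = 0.01,
                                     d0 = NULL) {
  logexpr <- as.matrix(logexpr)
  if (length(intersect(groupA, groupB))) stop_named("groups overlap")
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop_named("each group needs at least 2 samples")
  }
  A <- logexpr[, groupA, drop = FALSE]
  B <- logexpr[, groupB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums((A - mA)^2)
  ssB <- rowSums((B - mB)^2)
  d <- nA + nB - 2
  s2 <- (ssA + ssB) / d

  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, d)
  } else {
    prior <- list(d0 = d0, s0sq = fit_variance_prior(s2, d, d0_fixed = d0)$s0sq)
  }
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s0sq, length(s2))
  } else if (prior$d0 == 0) {
    s2
  } else {
    (prior$d0 * prior$s0sq + d * s2) / (prior$d0 + d)
  }
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  logfc <- mA - mB
  tstat <- ifelse(se > 0, logfc / se, 0)
  df_total <- prior$d0 + d
  p <- if (is.infinite(df_total)) {
    2 * pnorm(-abs(tstat))
  } else {
    2 * pt(-abs(tstat), df = df_total)
  }
  q <- bh_adjust(p)
  direction <- ifelse(q <= q_cut & logfc < 0, "under",
               ifelse(q <= q_cut & logfc > 0, "over", "unchanged"))
  res <- data.frame(gene = rownames(logexpr) %||% seq_along(p),
                    logfc = logfc, t = tstat, p = p, q = q,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "d0") <- prior$d0
  attr(res, "s0sq") <- prior$s0sq
  class(res) <- c("de_result", "data.frame")
  res
}

# Moment fit of the scaled-F prior on log sample variances:
# Var(log s^2) = trigamma(d/2) + trigamma(d0/2), solved for d0 by Newton;
# s0^2 from the mean of log s^2 with the digamma bias corrections.
fit_variance_prior <- function(s2, d, d0_fixed = NULL) {
  ok <- is.finite(s2) & s2 > 0
  e <- log(s2[ok])
  if (!length(e)) return(list(d0 = Inf, s0sq = mean(s2)))
  ve <- var(e)
  if (is.null(d0_fixed)) {
    target <- ve - trigamma(d / 2)
    d0 <- if (!is.finite(ve) || target <= 0) Inf else 2 * trigamma_inverse(target)
  } else {
    d0 <- d0_fixed
  }
  corr_d0 <- if (is.infinite(d0) || d0 == 0) 0 else digamma(d0 / 2) - log(d0 / 2)
  s0sq <- exp(mean(e) - (digamma(d / 2) - log(d / 2)) + corr_d0)
  list(d0 = d0, s0sq = s0sq)
}

trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; output order matches
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_named("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Under/over gene sets of several DE results and their Venn partition
#'
#' @param results named list of [moderated_two_group_test()] results sharing
#'   one gene universe.
#' @param threshold q-value cutoff (default 0.01).
#' @return list with `sets` (per result, `under` and `over` gene vectors)
#'   and `venn` (per direction, region counts keyed by the subset of result
#'   names, e.g. `"left+right"`).
#' @export
de_sets_and_venn <- function(results, threshold = 0.01) {
  stopifnot(length(results) >= 1)
  if (is.null(names(results))) names(results) <- paste0("set", seq_along(results))
  universes <- lapply(results, function(r) sort(r$gene))
  if (!all(vapply(universes, identical, logical(1), y = universes[[1]]))) {
    stop_named("DE results do not share one gene universe")
  }
  sets <- lapply(results, function(r) {
    list(under = r$gene[r$q <= threshold & r$logfc < 0],
         over = r$gene[r$q <= threshold & r$logfc > 0])
  })
  venn <- lapply(c(under = "under", over = "over"), function(dir) {
    venn_regions(lapply(sets, `[[`, dir))
  })
  list(sets = sets, venn = venn)
}

#' Region counts of the Venn partition of several sets
#'
#' @param sets named list of character vectors.
#' @return named integer vector: one count per non-empty membership pattern,
#'   keyed by the `+`-joined set names.
#' @export
venn_regions <- function(sets) {
  nm <- names(sets)
  all_items <- unique(unlist(sets))
  patterns <- lapply(seq_along(nm), function(i) all_items %in% sets[[i]])
  key <- apply(do.call(cbind, patterns), 1, function(m) paste(nm[m], collapse = "+"))
  counts <- integer(0)
  combos <- unlist(lapply(seq_along(nm), function(k) {
    apply(combn(nm, k), 2, paste, collapse = "+")
  }))
  for (cb in combos) counts[cb] <- sum(key == cb)
  counts
}

#' Fisher overrepresentation test of annotation categories in a gene set
#'
#' One 2x2 table per category (in-set x in-category over the universe),
#' one-sided (`greater`) Fisher's exact test by default; no correction
#' across categories.
#'
#' @param geneset character vector, a subset of `universe`.
#' @param universe character vector of all measured genes.
#' @param annot named list: category -> gene vector.
#' @param alternative `"greater"` (overrepresentation, default) or
#'   `"two.sided"`.
#' @return data frame `category`, `n_set`, `n_category`, `overlap`, `odds`,
#'   `p`.
#' @export
category_enrichment <- function(geneset, universe, annot,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(universe)) stop_named("empty gene universe")
  universe <- unique(universe)
  geneset <- intersect(unique(geneset), universe)
  rows <- lapply(names(annot), function(cat) {
    members <- intersect(unique(annot[[cat]]), universe)
    a <- length(intersect(geneset, members))
    b <- length(geneset) - a
    c_ <- length(members) - a
    d_ <- length(universe) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d_), 2, 2), alternative = alternative)
    data.frame(category = cat, n_set = length(geneset),
               n_category = length(members), overlap = a,
               odds = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
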