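# Centroid-correlation molecular subtyping: G-CIMP positivity, four-class
# Verhaak-style assignment, and initial -> recurrent transition tables.

#' Tumor log-ratio profiles versus the average normal reference
#'
#' Per gene: tumor log2 expression minus the mean of the normal reference
#' samples.
#'
#' @param logexpr log2 expression matrix, genes x samples.
#' @param normals character vector of normal reference sample ids (>= 1).
#' @param tumors tumor sample ids (default: all non-normal columns).
#' @return matrix genes x tumors of log-ratios.
#' @export
tumor_logratio_vs_normal <- function(logexpr, normals, tumors = NULL) {
  logexpr <- as.matrix(logexpr)
  if (!length(normals)) stop_named("no normal reference samples given")
  missing <- setdiff(normals, colnames(logexpr))
  if (length(missing)) {
    stop_named("unknown normal sample(s): %s", paste(missing, collapse = ", "))
  }
  tumors <- tumors %||% setdiff(colnames(logexpr), normals)
  ref <- rowMeans(logexpr[, normals, drop = FALSE])
  logexpr[, tumors, drop = FALSE] - ref
}

#' G-CIMP call by signature correlation
#'
#' Pearson correlation between a tumor log-ratio profile and the G-CIMP
#' signature centroid, over the genes shared by both; the tumor is G-CIMP
#' positive iff the correlation is strictly positive.
#'
#' @param logratio named per-gene log-ratio vector for one tumor.
#' @param sig named numeric signature centroid.
#' @param min_genes minimum shared genes (default 3); fewer gives an `NA`
#'   call with a warning.
#' @return list `r` (correlation), `positive` (logical, `NA` when
#'   unclassifiable).
#' @export
gcimp_call <- function(logratio, sig, min_genes = 3) {
  shared <- intersect(names(logratio), names(sig))
  if (length(shared) < min_genes) {
    warning(sprintf("only %d shared signature genes: unclassifiable",
                    length(shared)))
    return(list(r = NA_real_, positive = NA))
  }
  r <- cor(logratio[shared], sig[shared])
  list(r = r, positive = r > 0)
}

#' Assign a tumor to the maximally correlated subtype class
#'
#' Pearson correlation against each class centroid over the genes shared
#' with the measured profile; the tumor is assigned to the class with the
#' greatest correlation when that correlation exceeds `min_r`, otherwise it
#' is `unclassifiable` (as are exact ties).
#'
#' @param logratio named per-gene log-ratio vector for one tumor.
#' @param sigs centroid matrix (signature genes x classes) or named list of
#'   named numeric centroids.
#' @param min_r minimum correlation for a call (default 0: strictly
#'   positive correlation required).
#' @return list `class` (or `"unclassifiable"`), `r` (per-class
#'   correlations).
#' @export
verhaak_assign <- function(logratio, sigs, min_r = 0) {
  if (is.matrix(sigs)) {
    sigs <- setNames(lapply(seq_len(ncol(sigs)), function(j) {
      setNames(sigs[, j], rownames(sigs))
    }), colnames(sigs))
  }
  if (length(sigs) < 2) stop_named("need at least 2 subtype signatures")
  r <- vapply(sigs, function(cen) {
    shared <- intersect(names(logratio), names(cen))
    if (length(shared) < 3) return(NA_real_)
    cor(logratio[shared], cen[shared])
  }, numeric(1))
  rmax <- max(r, na.rm = TRUE)
  top <- names(r)[!is.na(r) & r == rmax]
  cls <- if (rmax > min_r && length(top) == 1L) top else "unclassifiable"
  list(class = cls, r = r)
}

#' Subtype every tumor of a cohort
#'
#' @param logratios matrix genes x tumors from [tumor_logratio_vs_normal()].
#' @param sigs class centroids (see [verhaak_assign()]).
#' @param gcimp_sig optional G-CIMP centroid; adds `gcimp_r`/`gcimp` columns.
#' @param min_r minimum correlation for a class call.
#' @return data frame of class `subtype_calls`: `sample`, per-class `r_*`
#'   columns, `class`, and optionally the G-CIMP call.
#' @export
subtype_cohort <- function(logratios, sigs, gcimp_sig = NULL, min_r = 0) {
  rows <- lapply(colnames(logratios), function(smp) {
    v <- setNames(logratios[, smp], rownames(logratios))
    va <- verhaak_assign(v, sigs, min_r = min_r)
    row <- data.frame(sample = smp, t(va$r), class = va$class,
                      stringsAsFactors = FALSE, check.names = FALSE)
    names(row)[2:(1 + length(va$r))] <- paste0("r_", names(va$r))
    if (!is.null(gcimp_sig)) {
      gc <- gcimp_call(v, gcimp_sig)
      row$gcimp_r <- gc$r
      row$gcimp <- gc$positive
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("subtype_calls", "data.frame")
  out
}

#' Initial-class by recurrent-class transition counts of matched pairs
#'
#' Pairs with an unclassifiable member are excluded from the matrix and
#' reported in the `excluded` attribute.
#'
#' @param calls a [subtype_cohort()] result (columns `sample`, `class`).
#' @param pairs data frame `patient`, `initial`, `recurrent`.
#' @param classes class label order for the matrix (default: classes seen).
#' @return matrix of counts, initial classes in rows, recurrent in columns;
#'   attribute `excluded` lists the dropped patients.
#' @export
transition_table <- function(calls, pairs, classes = NULL) {
  cls <- setNames(calls$class, calls$sample)
  ci <- cls[pairs$initial]
  cr <- cls[pairs$recurrent]
  ok <- !is.na(ci) & !is.na(cr) & ci != "unclassifiable" & cr != "unclassifiable"
  classes <- classes %||% sort(unique(c(ci[ok], cr[ok])))
  tab <- table(factor(ci[ok], levels = classes),
               factor(cr[ok], levels = classes))
  m <- unclass(as.matrix(tab))
  names(dimnames(m)) <- c("initial", "recurrent")
  attr(m, "excluded") <- pairs$patient[!ok]
  m
}
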