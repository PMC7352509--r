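# Unsupervised structure: correlation distance, Ward (ward.D2) trees,
# k-cluster cuts, matched-pair adjacency, bootstrap subcluster support.

#' One-minus-Pearson correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)`, in `[0, 2]`, computed between the rows of `X`.
#'
#' @param X matrix samples x features (at least 2 features).
#' @return a symmetric distance matrix with zero diagonal.
#' @export
corr_distance <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop_named("corr_distance needs at least 2 features")
  sds <- apply(X, 1, sd)
  if (any(sds == 0)) {
    bad <- rownames(X)[sds == 0] %||% which(sds == 0)
    stop_named("constant sample vector(s): %s", paste(bad, collapse = ", "))
  }
  D <- 1 - cor(t(X))
  diag(D) <- 0
  D
}

#' Ward (ward.D2) hierarchical clustering of a distance matrix
#'
#' Agglomerates with the ward.D2 Lance-Williams update (squared
#' dissimilarities inside the recurrence, heights on the original scale).
#'
#' @param D symmetric distance matrix (or `dist`).
#' @return an `hclust` tree.
#' @export
ward_tree <- function(D) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
      stop_named("distance matrix must be symmetric")
    }
    D <- as.dist(D)
  }
  hclust(D, method = "ward.D2")
}

#' Cut a dendrogram into k major clusters
#'
#' Removes the `k - 1` highest merges, yielding exactly `k` clusters.
#'
#' @param tree an `hclust` tree.
#' @param k number of clusters (1..n).
#' @return named integer vector of cluster labels per sample.
#' @export
cut_major_clusters <- function(tree, k) {
  n <- length(tree$labels %||% tree$order)
  if (k < 1 || k > n) stop_named("k must be in 1..%d", n)
  cutree(tree, k = k)
}

# leaf sets of every internal node, as sorted label vectors
node_leaf_sets <- function(tree) {
  n <- nrow(tree$merge) + 1L
  labels <- tree$labels %||% as.character(seq_len(n))
  sets <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    members <- unlist(lapply(tree$merge[i, ], function(m) {
      if (m < 0) labels[-m] else sets[[m]]
    }))
    sets[[i]] <- sort(members)
  }
  sets
}

#' Classify how each patient-matched pair sits in a tree
#'
#' A pair clusters `"direct"` when some internal node's leaf set is exactly
#' the two samples; otherwise the pair is `"same-cluster"` or
#' `"different-cluster"` according to co-membership at a k-cluster cut.
#'
#' @param tree `hclust` tree over samples.
#' @param pairs data frame with columns `patient`, `initial`, `recurrent`
#'   (sample ids).
#' @param k number of major clusters for co-membership (default 3).
#' @return data frame `patient`, `status`.
#' @export
matched_pair_adjacency <- function(tree, pairs, k = 3) {
  labels <- tree$labels
  missing <- setdiff(c(pairs$initial, pairs$recurrent), labels)
  if (length(missing)) {
    stop_named("unknown sample id(s): %s", paste(missing, collapse = ", "))
  }
  sets <- node_leaf_sets(tree)
  two_sets <- sets[lengths(sets) == 2L]
  cl <- cut_major_clusters(tree, k)
  status <- vapply(seq_len(nrow(pairs)), function(i) {
    duo <- sort(c(pairs$initial[i], pairs$recurrent[i]))
    if (any(vapply(two_sets, identical, logical(1), y = duo))) return("direct")
    if (cl[duo[1]] == cl[duo[2]]) "same-cluster" else "different-cluster"
  }, character(1))
  data.frame(patient = pairs$patient, status = status, stringsAsFactors = FALSE)
}

#' Write a dendrogram as Newick with merge heights
#'
#' @param tree an `hclust` tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Bootstrap support of dendrogram nodes
#'
#' Features are resampled with replacement `B` times; each replicate is
#' re-clustered with the same distance and linkage, and a node's support is
#' the fraction of replicate trees containing its exact leaf set (plain
#' bootstrap probability).
#'
#' @param X matrix samples x features the tree was built from.
#' @param tree the original `hclust` tree (from [ward_tree()] on
#'   [corr_distance()] of `X`).
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return numeric vector of per-node support fractions (one per internal
#'   node, in `tree$merge` order).
#' @export
bootstrap_support <- function(X, tree, B = 100, seed = 1) {
  X <- as.matrix(X)
  orig <- node_leaf_sets(tree)
  hits <- numeric(length(orig))
  for (b in seq_len(B)) {
    idx <- with_substream(seed, paste0("boot:", b),
                          sample.int(ncol(X), ncol(X), replace = TRUE))
    rep_tree <- ward_tree(corr_distance(X[, idx, drop = FALSE]))
    rep_sets <- node_leaf_sets(rep_tree)
    keys <- vapply(rep_sets, paste, character(1), collapse = "\r")
    ok <- vapply(orig, function(s) paste(s, collapse = "\r") %in% keys,
                 logical(1))
    hits <- hits + ok
  }
  hits / B
}
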