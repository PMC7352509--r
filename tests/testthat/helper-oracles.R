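# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, direct formulas) kept separate from the
# package's own code paths.

# Exhaustive 3^T path enumeration for the Gaussian HMM: log-likelihood and
# per-position posterior state marginals.
oracle_hmm_enumerate <- function(x, params) {
  T_ <- length(x)
  K <- 3
  paths <- as.matrix(expand.grid(rep(list(1:K), T_)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(params$pi[s[1]]) +
      dnorm(x[1], params$mu[s[1]], sqrt(params$sigma2[s[1]]), log = TRUE)
    if (T_ > 1) {
      for (t in 2:T_) {
        lp <- lp + log(params$A[s[t - 1], s[t]]) +
          dnorm(x[t], params$mu[s[t]], sqrt(params$sigma2[s[t]]), log = TRUE)
      }
    }
    lp
  })
  m <- max(logp)
  loglik <- m + log(sum(exp(logp - m)))
  w <- exp(logp - loglik)
  gamma <- matrix(0, T_, K)
  for (t in 1:T_) {
    for (k in 1:K) gamma[t, k] <- sum(w[paths[, t] == k])
  }
  list(loglik = loglik, gamma = gamma)
}

# Naive ward.D2 agglomeration: Lance-Williams recurrence on squared
# dissimilarities, heights on the original scale, merging the globally
# closest pair at each step. Returns sorted merge heights and the set of
# internal-node leaf sets (as sorted labels collapsed to strings).
oracle_ward <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  S <- D^2
  clusters <- lapply(seq_len(n), function(i) labels[i])
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  node_sets <- character(0)
  while (length(active) > 1) {
    best <- c(NA, NA); best_val <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (S[i, j] < best_val) { best_val <- S[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(S[i, j]))
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    node_sets <- c(node_sets, paste(merged, collapse = "|"))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      S_new <- ((ni + nk) * S[i, k] + (nj + nk) * S[j, k] - nk * S[i, j]) /
        (ni + nj + nk)
      S[i, k] <- S[k, i] <- S_new
    }
    clusters[[i]] <- merged
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  list(heights = sort(heights), node_sets = sort(node_sets))
}

hclust_node_sets <- function(tree) {
  n <- nrow(tree$merge) + 1L
  labels <- tree$labels
  sets <- vector("list", nrow(tree$merge))
  out <- character(nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    members <- unlist(lapply(tree$merge[i, ], function(m) {
      if (m < 0) labels[-m] else sets[[m]]
    }))
    sets[[i]] <- sort(members)
    out[i] <- paste(sets[[i]], collapse = "|")
  }
  sort(out)
}

# Textbook BH step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  ranked <- p[o] * n / seq_len(n)
  ranked <- rev(cummin(rev(ranked)))
  q[o] <- pmin(ranked, 1)
  q
}

# Hypergeometric upper tail P(X >= a) by direct summation of choose terms.
oracle_hyper_tail <- function(a, n_set, n_cat, N) {
  ks <- a:min(n_set, n_cat)
  if (a > min(n_set, n_cat)) return(0)
  sum(choose(n_cat, ks) * choose(N - n_cat, n_set - ks)) / choose(N, n_set)
}

# Cluster labels agree with truth exactly up to relabeling.
perfect_partition_match <- function(cl, truth) {
  tab <- table(cl, truth)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Small cohort spec for fast tests.
small_spec <- function(n_patients = 6, n_genes = 400, seed = 1, ...) {
  cohort_spec(n_patients = n_patients, n_genes = n_genes, seed = seed,
              signature_truth = list(effect = 2, class_effect = 1.5,
                                     gcimp_effect = 0.75,
                                     n_subgroup_genes = 30,
                                     n_class_genes = 40,
                                     n_gcimp_genes = 15),
              ...)
}

random_hmm_params <- function() {
  A <- matrix(runif(9, 0.05, 1), 3, 3)
  A <- A / rowSums(A)
  pi <- runif(3, 0.05, 1); pi <- pi / sum(pi)
  mu <- sort(rnorm(3, c(-3, 0, 3), 0.5))
  hmm_params(pi = pi, A = A, mu = mu, sigma2 = runif(3, 0.3, 1.5))
}
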