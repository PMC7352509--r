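# Three-state Gaussian HMM over chromosomally ordered per-pair expression
# log-ratios: likelihood, multi-profile Baum-Welch, posterior decoding.
#
# Chromosomes are treated as independent sequences, each restarting from
# the initial state distribution: the dependency the model exploits is
# local chromosomal proximity, which does not carry across chromosome
# boundaries. Set `concat_genome = TRUE` to chain a whole profile instead.

#' Per-pair log2 expression ratio profiles (recurrent vs. initial)
#'
#' @param logexpr normalized log2 expression matrix, genes x samples; rows
#'   must be in gene-map order.
#' @param pairs data frame `patient`, `initial`, `recurrent` (sample ids).
#' @param gene_map matching [build_gene_map()] result.
#' @return a `pair_profiles` object (`values` genes x patients).
#' @export
pair_logratio <- function(logexpr, pairs, gene_map) {
  logexpr <- as.matrix(logexpr)
  for (i in seq_len(nrow(pairs))) {
    miss <- setdiff(c(pairs$initial[i], pairs$recurrent[i]), colnames(logexpr))
    if (length(miss)) {
      stop_named("patient %s: missing sample(s) %s", pairs$patient[i],
                 paste(miss, collapse = ", "))
    }
  }
  values <- logexpr[, pairs$recurrent, drop = FALSE] -
    logexpr[, pairs$initial, drop = FALSE]
  colnames(values) <- pairs$patient
  structure(list(values = values, states = NULL, gene_map = gene_map,
                 patients = pairs$patient),
            class = "pair_profiles")
}

# split a profile matrix into per-chromosome row index chunks
profile_chunks <- function(gene_map, n_genes, concat_genome = FALSE) {
  if (concat_genome || is.null(gene_map)) return(list(seq_len(n_genes)))
  b <- chrom_boundaries(gene_map)
  lapply(seq_len(nrow(b)), function(i) b$first[i]:b$last[i])
}

emission_logdens <- function(x, params) {
  vapply(1:3, function(k) {
    dnorm(x, params$mu[k], sqrt(params$sigma2[k]), log = TRUE)
  }, numeric(length(x)))
}

#' Log-likelihood of one log-ratio profile under the HMM
#'
#' Log-space forward algorithm, summed over chromosomes (each an
#' independent sequence restarting from the initial distribution).
#'
#' @param x numeric profile in gene-map order, or a one-column slice of a
#'   `pair_profiles` object.
#' @param params [hmm_params()].
#' @param gene_map gene map defining chromosome boundaries (`NULL` treats
#'   `x` as a single sequence).
#' @param concat_genome chain the whole profile as one sequence.
#' @return log-likelihood.
#' @export
sequence_loglik <- function(x, params, gene_map = NULL, concat_genome = FALSE) {
  validate_hmm_params(params)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop_named("profile contains non-finite values")
  chunks <- profile_chunks(gene_map, length(x), concat_genome)
  logpi <- log(params$pi)
  logA <- log(params$A)
  total <- 0
  for (rows in chunks) {
    logB <- emission_logdens(x[rows], params)
    if (!is.matrix(logB)) logB <- matrix(logB, nrow = 1)
    total <- total + .hmm_forward_cpp(logB, logpi, logA)
  }
  total
}

#' Fit the HMM to a set of log-ratio profiles by pooled Baum-Welch
#'
#' One model is trained across all profiles: expected counts from every
#' profile and chromosome are pooled in each M-step. Initial distribution,
#' transition matrix, means and variances are all re-estimated (switchable);
#' state identity (under < unchanged < over) is maintained by relabeling
#' states whenever an M-step breaks the mean ordering.
#'
#' @param profiles a `pair_profiles` object, or a numeric matrix genes x
#'   profiles (then supply `gene_map`).
#' @param init initial [hmm_params()] (default: means -3/0/3, unit
#'   variances, 0.9 self-transitions, uniform start).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol stop when the total log-likelihood gain falls below this
#'   (default 1e-4).
#' @param gene_map gene map when `profiles` is a bare matrix.
#' @param concat_genome chain whole profiles instead of per-chromosome
#'   sequences.
#' @param estimate_pi,estimate_A re-estimate the initial distribution /
#'   transition matrix (both default TRUE).
#' @param tie_variances constrain all states to one shared emission
#'   variance.
#' @param variance_floor lower clamp for emission variances (default 1e-4;
#'   clamping warns).
#' @return list with `params`, `loglik_trace` (one value per iteration),
#'   `n_iter`, `converged`.
#' @export
fit_hmm <- function(profiles, init = hmm_params(), max_iter = 200, tol = 1e-4,
                    gene_map = NULL, concat_genome = FALSE,
                    estimate_pi = TRUE, estimate_A = TRUE,
                    tie_variances = FALSE, variance_floor = 1e-4) {
  pf <- as_profile_matrix(profiles, gene_map)
  validate_hmm_params(init)
  chunks <- profile_chunks(pf$gene_map, nrow(pf$values), concat_genome)
  params <- init
  trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    logpi <- log(params$pi); logA <- log(params$A)
    loglik <- 0
    pi_acc <- numeric(3)
    xi_acc <- matrix(0, 3, 3)
    w_acc <- numeric(3)
    wx_acc <- numeric(3)
    wx2_acc <- numeric(3)
    for (j in seq_len(ncol(pf$values))) {
      x <- pf$values[, j]
      for (rows in chunks) {
        xs <- x[rows]
        logB <- emission_logdens(xs, params)
        if (!is.matrix(logB)) logB <- matrix(logB, nrow = 1)
        fb <- .hmm_fwdbwd_cpp(logB, logpi, logA)
        loglik <- loglik + fb$loglik
        pi_acc <- pi_acc + fb$gamma[1, ]
        xi_acc <- xi_acc + fb$xi
        w_acc <- w_acc + colSums(fb$gamma)
        wx_acc <- wx_acc + colSums(fb$gamma * xs)
        wx2_acc <- wx2_acc + colSums(fb$gamma * xs^2)
      }
    }
    trace <- c(trace, loglik)

    # states with (numerically) no posterior mass keep their parameters
    dead <- w_acc < 1e-12
    mu <- ifelse(dead, params$mu, wx_acc / w_acc)
    sigma2 <- ifelse(dead, params$sigma2, wx2_acc / w_acc - mu^2)
    if (tie_variances) sigma2 <- rep(sum(wx2_acc - w_acc * mu^2) / sum(w_acc), 3)
    if (any(sigma2 < variance_floor)) {
      warning("emission variance clamped to floor")
      sigma2 <- pmax(sigma2, variance_floor)
    }
    new_pi <- if (estimate_pi) pi_acc / sum(pi_acc) else params$pi
    new_A <- params$A
    if (estimate_A) {
      rs <- rowSums(xi_acc)
      alive <- rs > 1e-12
      new_A[alive, ] <- xi_acc[alive, , drop = FALSE] / rs[alive]
    }
    if (any(diff(mu[order(mu)]) == 0)) {
      # collapsed means cannot be ordered into distinct states
      mu <- mu + c(-1e-9, 0, 1e-9)
    }
    ord <- order(mu)
    params <- structure(list(pi = new_pi[ord], A = new_A[ord, ord],
                             mu = mu[ord], sigma2 = sigma2[ord],
                             states = init$states),
                        class = "hmm_params")
    validate_hmm_params(params)

    if (iter > 1 && trace[iter] - trace[iter - 1] < tol) {
      converged <- TRUE
      break
    }
  }
  list(params = params, loglik_trace = trace, n_iter = length(trace),
       converged = converged)
}

#' Posterior decoding of expression states for each profile
#'
#' Forward-backward per chromosome; each gene gets its three state
#' posteriors and the maximum-posterior label, coded -1 (under), 0
#' (unchanged), +1 (over). Posterior ties resolve to `unchanged`.
#'
#' @param profiles a `pair_profiles` object or matrix (see [fit_hmm()]).
#' @param params [hmm_params()].
#' @param gene_map gene map when `profiles` is a bare matrix.
#' @param concat_genome chain whole profiles.
#' @return list of class `posterior_decoding`: `posterior` (genes x 3 x
#'   profiles array), `labels` (genes x profiles, -1/0/+1), `loglik`.
#' @export
posterior_decode <- function(profiles, params, gene_map = NULL,
                             concat_genome = FALSE) {
  pf <- as_profile_matrix(profiles, gene_map)
  validate_hmm_params(params)
  chunks <- profile_chunks(pf$gene_map, nrow(pf$values), concat_genome)
  logpi <- log(params$pi); logA <- log(params$A)
  n_genes <- nrow(pf$values); n_prof <- ncol(pf$values)
  post <- array(NA_real_, c(n_genes, 3, n_prof),
                dimnames = list(rownames(pf$values), params$states,
                                colnames(pf$values)))
  labels <- matrix(NA_integer_, n_genes, n_prof,
                   dimnames = dimnames(pf$values))
  total <- 0
  for (j in seq_len(n_prof)) {
    for (rows in chunks) {
      logB <- emission_logdens(pf$values[rows, j], params)
      if (!is.matrix(logB)) logB <- matrix(logB, nrow = 1)
      fb <- .hmm_fwdbwd_cpp(logB, logpi, logA)
      total <- total + fb$loglik
      g <- fb$gamma
      post[rows, , j] <- g
      best <- max.col(g, ties.method = "first")
      # resolve posterior ties toward "unchanged"
      ties <- abs(g[cbind(seq_len(nrow(g)), best)] - g[, 2]) < 1e-12 & best != 2L
      best[ties] <- 2L
      labels[rows, j] <- best - 2L
    }
  }
  structure(list(posterior = post, labels = labels, loglik = total,
                 states = params$states),
            class = "posterior_decoding")
}

as_profile_matrix <- function(profiles, gene_map = NULL) {
  if (inherits(profiles, "pair_profiles")) {
    list(values = profiles$values, gene_map = profiles$gene_map)
  } else {
    list(values = as.matrix(profiles), gene_map = gene_map)
  }
}
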