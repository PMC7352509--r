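#' Parameters of the three-state Gaussian expression-state HMM
#'
#' The hidden states are, in fixed order, `under` (underexpressed in the
#' recurrent relative to the initial tumor), `unchanged`, and `over`
#' (overexpressed). Emissions are state-specific normal densities on the
#' per-gene log2 expression ratio of recurrent versus initial tumor.
#'
#' @param pi initial state distribution (length 3, sums to 1).
#' @param A 3x3 row-stochastic transition matrix.
#' @param mu state emission means; must be strictly increasing so the state
#'   labels keep their meaning (default -3, 0, 3 log2 units).
#' @param sigma2 state emission variances (> 0).
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(pi = rep(1 / 3, 3),
                       A = matrix(c(0.9, 0.05, 0.05,
                                    0.05, 0.9, 0.05,
                                    0.05, 0.05, 0.9), 3, 3, byrow = TRUE),
                       mu = c(-3, 0, 3),
                       sigma2 = c(1, 1, 1)) {
  p <- structure(list(pi = as.numeric(pi), A = unname(as.matrix(A)),
                      mu = as.numeric(mu), sigma2 = as.numeric(sigma2),
                      states = c("under", "unchanged", "over")),
                 class = "hmm_params")
  validate_hmm_params(p)
  p
}

#' Validate HMM parameters
#'
#' @param p an `hmm_params` object (or bare list with the same fields).
#' @param tol tolerance for stochasticity checks.
#' @return `p`, invisibly; errors with an informative message otherwise.
#' @export
validate_hmm_params <- function(p, tol = 1e-10) {
  if (length(p$pi) != 3L || any(p$pi < 0) || abs(sum(p$pi) - 1) > tol) {
    stop_named("invalid HMM parameters: pi must be a length-3 distribution")
  }
  if (!is.matrix(p$A) || any(dim(p$A) != 3L) || any(p$A < 0) ||
      any(abs(rowSums(p$A) - 1) > tol)) {
    stop_named("invalid HMM parameters: A must be a 3x3 row-stochastic matrix")
  }
  if (length(p$mu) != 3L || any(diff(p$mu) <= 0)) {
    stop_named("invalid HMM parameters: mu must be strictly increasing (under < unchanged < over)")
  }
  if (length(p$sigma2) != 3L || any(p$sigma2 <= 0)) {
    stop_named("invalid HMM parameters: sigma2 must be positive")
  }
  invisible(p)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("3-state Gaussian HMM parameters\n")
  cat("  pi:    ", paste(signif(x$pi, 4), collapse = "  "), "\n")
  cat("  mu:    ", paste(signif(x$mu, 4), collapse = "  "), "\n")
  cat("  sigma: ", paste(signif(sqrt(x$sigma2), 4), collapse = "  "), "\n")
  cat("  A:\n")
  print(signif(x$A, 4))
  invisible(x)
}
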