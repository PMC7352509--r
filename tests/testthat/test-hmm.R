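test_that("pair log-ratio profiles are plain per-gene differences", {
  gm <- build_gene_map(6, 2)
  X <- matrix(rnorm(6 * 4, 5), 6, 4,
              dimnames = list(gm$gene, c("P1-I", "P1-R", "P2-I", "P2-R")))
  pairs <- data.frame(patient = c("P1", "P2"),
                      initial = c("P1-I", "P2-I"),
                      recurrent = c("P1-R", "P2-R"))
  pf <- pair_logratio(X, pairs, gm)
  expect_equal(pf$values[, "P1"], X[, "P1-R"] - X[, "P1-I"])

  # identical tumors -> zero; constant shift -> constant; swap -> negation
  X2 <- X; X2[, "P2-R"] <- X2[, "P2-I"] + 2
  pf2 <- pair_logratio(X2, pairs, gm)
  expect_equal(unname(pf2$values[, "P2"]), rep(2, 6))
  swapped <- pair_logratio(X, transform(pairs, initial = recurrent,
                                        recurrent = initial), gm)
  expect_equal(swapped$values, -pf$values, ignore_attr = TRUE)

  expect_error(pair_logratio(X[, 1:3], pairs, gm), "P2.*missing|missing sample")
})

test_that("forward log-likelihood matches closed form and path enumeration", {
  p <- hmm_params()
  # length-1 sequence: log of the mixture density
  x1 <- 0.7
  expected <- log(sum(p$pi * dnorm(x1, p$mu, sqrt(p$sigma2))))
  expect_equal(sequence_loglik(x1, p), expected, tolerance = 1e-12)

  # translation invariance of means and observations
  set.seed(30)
  x <- rnorm(20)
  p_shift <- hmm_params(mu = p$mu + 5, sigma2 = p$sigma2, A = p$A, pi = p$pi)
  expect_equal(sequence_loglik(x, p), sequence_loglik(x + 5, p_shift),
               tolerance = 1e-10)

  # exhaustive 3^T oracle for short sequences, random parameters
  for (rep in 1:25) {
    prm <- random_hmm_params()
    T_ <- sample(1:6, 1)
    xx <- rnorm(T_, sample(prm$mu, T_, replace = TRUE), 1)
    expect_equal(sequence_loglik(xx, prm),
                 oracle_hmm_enumerate(xx, prm)$loglik, tolerance = 1e-8)
  }

  # chromosomes are independent restarts: loglik adds over chromosomes
  gm <- build_gene_map(6, 2)
  x6 <- rnorm(6)
  expect_equal(sequence_loglik(x6, p, gene_map = gm),
               sequence_loglik(x6[1:3], p) + sequence_loglik(x6[4:6], p),
               tolerance = 1e-12)
})

test_that("posterior decoding equals the path-enumeration oracle", {
  set.seed(31)
  for (rep in 1:25) {
    prm <- random_hmm_params()
    T_ <- sample(2:6, 1)
    x <- rnorm(T_, 0, 2)
    dec <- posterior_decode(matrix(x, ncol = 1), prm)
    oracle <- oracle_hmm_enumerate(x, prm)
    expect_equal(unname(dec$posterior[, , 1]), oracle$gamma, tolerance = 1e-8)
    expect_lt(max(abs(rowSums(dec$posterior[, , 1]) - 1)), 1e-10)
  }
})

test_that("decoding hits planted states in the small-variance limit and is
           invariant to chromosome order", {
  p_tight <- hmm_params(sigma2 = rep(1e-6, 3))
  set.seed(32)
  states <- sample(1:3, 50, replace = TRUE)
  x <- p_tight$mu[states]
  dec <- posterior_decode(matrix(x, ncol = 1), p_tight)
  expect_equal(unname(dec$labels[, 1]), states - 2L)

  # chromosome processing order does not change per-gene posteriors
  gm <- build_gene_map(50, 5)
  p <- hmm_params(sigma2 = rep(0.5, 3))
  dec_fwd <- posterior_decode(matrix(x, ncol = 1), p, gene_map = gm)
  blocks <- split(seq_len(50), gm$chrom)
  perm <- unlist(rev(blocks))
  gm_perm <- gm[perm, ]
  dec_rev <- posterior_decode(matrix(x[perm], ncol = 1), p, gene_map = gm_perm)
  expect_equal(dec_rev$posterior[order(perm), , 1], dec_fwd$posterior[, , 1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("an i.i.d. chain decodes to the per-gene Bayes classifier", {
  pi <- c(0.2, 0.5, 0.3)
  A <- rbind(pi, pi, pi)
  p <- hmm_params(pi = pi, A = A, sigma2 = c(0.8, 0.5, 0.8))
  set.seed(33)
  x <- rnorm(200, 0, 2.5)
  dec <- posterior_decode(matrix(x, ncol = 1), p)
  dens <- vapply(1:3, function(k) pi[k] * dnorm(x, p$mu[k], sqrt(p$sigma2[k])),
                 numeric(200))
  bayes <- dens / rowSums(dens)
  expect_equal(unname(dec$posterior[, , 1]), bayes, tolerance = 1e-10)
})

test_that("Baum-Welch is monotone and stable at a fixed point", {
  spec <- small_spec(n_patients = 4, n_genes = 300)
  pf <- simulate_pair_profiles(spec)
  truth <- spec$hmm_truth

  fit <- fit_hmm(pf, init = truth, max_iter = 30)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # initialized at the generating parameters, the first move is small
  expect_lt(max(abs(fit$params$mu - truth$mu)), 0.25)

  fit2 <- fit_hmm(pf, init = hmm_params(), max_iter = 60)
  expect_true(all(diff(fit2$loglik_trace) >= -1e-8))
  expect_true(fit2$converged)
  expect_lt(max(abs(fit2$params$mu - truth$mu)), 0.3)
  dec <- posterior_decode(pf, fit2$params)
  expect_gt(mean(dec$labels == pf$states), 0.95)
})

test_that("variance floor clamps degenerate emissions with a warning", {
  # almost all mass at exactly the middle state's mean collapses its variance
  x <- c(rep(0, 60), -3, 3)
  w <- capture_warnings(
    fit <- fit_hmm(matrix(x, ncol = 1), init = hmm_params(), max_iter = 40))
  expect_true(any(grepl("variance clamped", w)))
  expect_true(all(fit$params$sigma2 >= 1e-4))
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("invalid parameters are rejected by likelihood and decoding", {
  p <- hmm_params()
  bad <- p; bad$A[1, ] <- c(0.5, 0.5, 0.5)
  expect_error(sequence_loglik(rnorm(5), bad), "row-stochastic")
  expect_error(posterior_decode(matrix(rnorm(5), ncol = 1), bad),
               "row-stochastic")
  expect_error(sequence_loglik(c(1, NA), p), "non-finite")
})
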