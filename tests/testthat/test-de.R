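test_that("moderated test is well calibrated under the null", {
  set.seed(20)
  X <- matrix(rnorm(1000 * 8), 1000, 8,
              dimnames = list(paste0("g", 1:1000), paste0("s", 1:8)))
  res <- moderated_two_group_test(X, paste0("s", 1:4), paste0("s", 5:8))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1000))  # 1% critical value
})

test_that("degenerate genes and group validation behave", {
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  X[3, ] <- 5  # identical values in both groups
  res <- moderated_two_group_test(X, c("s1", "s2"), c("s3", "s4"))
  expect_equal(res$t[3], 0)
  expect_equal(res$p[3], 1)
  expect_error(moderated_two_group_test(X, c("s1", "s2"), c("s2", "s3")),
               "overlap")
  expect_error(moderated_two_group_test(X, "s1", c("s2", "s3")),
               "at least 2")
})

test_that("d0 limits reduce to the pooled-z and ordinary t tests", {
  set.seed(21)
  X <- matrix(rnorm(200 * 10, sd = rep(runif(200, 0.5, 2), 10)), 200, 10,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  A <- paste0("s", 1:5); B <- paste0("s", 6:10)

  # d0 = 0: ordinary pooled-variance t-test
  res0 <- moderated_two_group_test(X, A, B, d0 = 0)
  for (i in c(1, 50, 200)) {
    tt <- t.test(X[i, A], X[i, B], var.equal = TRUE)
    expect_equal(res0$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res0$t[i], unname(tt$statistic), tolerance = 1e-10)
  }

  # d0 = Inf: all genes share the prior variance, normal reference
  resInf <- moderated_two_group_test(X, A, B, d0 = Inf)
  s0 <- attr(resInf, "s0sq")
  z <- resInf$logfc / sqrt(s0 * (1 / 5 + 1 / 5))
  expect_equal(resInf$t, z, tolerance = 1e-12)
  expect_equal(resInf$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("variance-prior moment fit agrees with limma's squeezeVar", {
  set.seed(22)
  d <- 6
  s2 <- 0.5 * rchisq(1500, d) / d * exp(rnorm(1500, 0, 0.7))
  mine <- astropair:::fit_variance_prior(s2, d)
  ref <- limma::squeezeVar(s2, df = d)
  expect_equal(mine$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(mine$s0sq, ref$var.prior, tolerance = 1e-6)
  post <- (mine$d0 * mine$s0sq + d * s2) / (mine$d0 + d)
  expect_equal(post, ref$var.post, tolerance = 1e-10)
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")

  set.seed(23)
  for (rep in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # q >= p and q monotone in p-rank
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("DE sets and Venn regions match brute-force set algebra", {
  mk <- function(q, lfc) {
    structure(data.frame(gene = paste0("g", seq_along(q)), logfc = lfc,
                         t = 0, p = q, q = q,
                         direction = "unchanged", stringsAsFactors = FALSE),
              class = c("de_result", "data.frame"))
  }
  r1 <- mk(c(0.001, 0.001, 0.5, 0.001), c(-1, 2, 1, -1))
  r2 <- mk(c(0.001, 0.5, 0.001, 0.001), c(-2, 1, 3, 1))
  out <- de_sets_and_venn(list(a = r1, b = r2), threshold = 0.01)
  expect_setequal(out$sets$a$under, c("g1", "g4"))
  expect_setequal(out$sets$b$over, c("g3", "g4"))
  expect_equal(unname(out$venn$under[["a+b"]]), 1)  # g1
  expect_equal(unname(out$venn$under[["a"]]), 1)    # g4

  # identical results: everything in the common region
  same <- de_sets_and_venn(list(x = r1, y = r1))
  expect_equal(unname(same$venn$under[["x+y"]]), length(r1$gene[r1$q <= 0.01 & r1$logfc < 0]))
  expect_equal(unname(same$venn$under[["x"]]), 0)

  # random sets vs direct membership-pattern counting
  set.seed(24)
  universe <- paste0("g", 1:40)
  sets <- list(A = sample(universe, 15), B = sample(universe, 10),
               C = sample(universe, 20))
  vr <- venn_regions(sets)
  for (item in unique(unlist(sets))) {
    memb <- names(sets)[vapply(sets, function(s) item %in% s, logical(1))]
    key <- paste(memb, collapse = "+")
    expect_true(vr[[key]] >= 1)
  }
  expect_equal(sum(vr), length(unique(unlist(sets))))

  r3 <- mk(c(0.001, 0.5), c(1, 1))
  expect_error(de_sets_and_venn(list(r1, r3)), "universe")
})

test_that("Fisher enrichment equals the hypergeometric tail sum", {
  universe <- paste0("g", 1:100)
  annot <- list(cat10 = universe[1:10])
  geneset <- c(universe[1:5], universe[51:55])  # 5 of 10 in-category
  enr <- category_enrichment(geneset, universe, annot)
  expect_equal(enr$p, oracle_hyper_tail(5, 10, 10, 100), tolerance = 1e-12)

  # geneset identical to the category: maximal-overlap tail
  enr2 <- category_enrichment(universe[1:10], universe, annot)
  expect_equal(enr2$p, oracle_hyper_tail(10, 10, 10, 100), tolerance = 1e-12)

  # disjoint category: p = 1 for the greater side
  enr3 <- category_enrichment(universe[11:30], universe,
                              list(cat = universe[1:10]))
  expect_equal(enr3$p, 1)

  expect_error(category_enrichment("g1", character(0), annot), "empty")

  # random 2x2 tables with N <= 60 against the direct summation oracle
  set.seed(25)
  for (rep in 1:60) {
    N <- sample(10:60, 1)
    uni <- paste0("x", 1:N)
    n_cat <- sample(1:(N - 1), 1)
    n_set <- sample(1:(N - 1), 1)
    cat_genes <- sample(uni, n_cat)
    set_genes <- sample(uni, n_set)
    p <- category_enrichment(set_genes, uni, list(c = cat_genes))$p
    a <- length(intersect(set_genes, cat_genes))
    expect_equal(p, oracle_hyper_tail(a, n_set, n_cat, N), tolerance = 1e-12)
  }
})
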