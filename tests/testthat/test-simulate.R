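test_that("a fixed seed reproduces the cohort bit-identically", {
  spec <- small_spec()
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$expr, b$expr)
  expect_identical(a$segments, b$segments)
  expect_identical(a$samples, b$samples)
  expect_identical(simulate_pair_profiles(spec)$values,
                   simulate_pair_profiles(spec)$values)
})

test_that("zero-noise limit reproduces planted copy-number effects exactly", {
  ev <- data.frame(chrom = "chr10", start = NA_real_, end = NA_real_,
                   shift = 1, subgroup = NA, stage = "both",
                   stringsAsFactors = FALSE)
  spec <- cohort_spec(n_patients = 2, n_genes = 100, n_chromosomes = 10,
                      cna_truth = ev, cna_attenuation = 1,
                      noise_sd = 1e-15, pair_effect_sd = 0, seed = 7,
                      signature_truth = list(effect = 0, class_effect = 0,
                                             gcimp_effect = 0,
                                             n_subgroup_genes = 2,
                                             n_class_genes = 2,
                                             n_gcimp_genes = 2))
  co <- simulate_cohort(spec)
  gm <- co$gene_map
  on10 <- gm$gene[gm$chrom == "chr10"]
  off10 <- gm$gene[gm$chrom != "chr10"]
  tum <- co$samples$sample_id[co$samples$stage != "normal"]
  dev <- co$expr[, tum] - co$truth$baseline
  expect_lt(max(abs(dev[on10, ] - 1)), 1e-12)
  expect_lt(max(abs(dev[off10, ])), 1e-12)
})

test_that("adding patients never perturbs earlier samples' draws", {
  # discordance is allocated from the cohort tail, so hold it at zero to
  # compare the same planted design at two cohort sizes
  a <- simulate_cohort(small_spec(n_patients = 4, discordant_fraction = 0))
  b <- simulate_cohort(small_spec(n_patients = 6, discordant_fraction = 0))
  shared <- intersect(colnames(a$expr), colnames(b$expr))
  expect_identical(a$expr[, shared], b$expr[, shared])
})

test_that("HMM profile run lengths follow the planted geometric law", {
  A <- matrix(0.005, 3, 3); diag(A) <- 0.99
  spec <- cohort_spec(n_patients = 1, n_genes = 10000, n_chromosomes = 10,
                      hmm_truth = hmm_params(A = A, sigma2 = rep(0.49, 3)),
                      seed = 1,
                      signature_truth = list(effect = 0, class_effect = 0,
                                             gcimp_effect = 0,
                                             n_subgroup_genes = 2,
                                             n_class_genes = 2,
                                             n_gcimp_genes = 2))
  pf <- simulate_pair_profiles(spec)
  # drop the censored final run of each chromosome
  runs <- unlist(lapply(split(pf$states[, 1], pf$gene_map$chrom), function(s) {
    r <- rle(as.vector(s))$lengths
    if (length(r) > 1) r[-length(r)] else integer(0)
  }))
  # geometric with p = 0.01: mean 100, sd ~ sqrt(1-p)/p
  se <- (sqrt(0.99) / 0.01) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - 100), 3 * se)
})

test_that("first states follow the initial distribution and marginals the
           stationary distribution", {
  # many short chromosomes give many independent first-state draws
  spec <- cohort_spec(n_patients = 1, n_genes = 40000, n_chromosomes = 20000,
                      cna_truth = data.frame(chrom = "chr1", start = NA_real_,
                                             end = NA_real_, shift = 0,
                                             subgroup = NA, stage = "both"),
                      seed = 1,
                      signature_truth = list(effect = 0, class_effect = 0,
                                             gcimp_effect = 0,
                                             n_subgroup_genes = 2,
                                             n_class_genes = 2,
                                             n_gcimp_genes = 2))
  pf <- simulate_pair_profiles(spec)
  firsts <- pf$states[chrom_starts <- !duplicated(pf$gene_map$chrom), 1]
  freq <- table(factor(firsts, levels = -1:1)) / length(firsts)
  se <- sqrt((1 / 3) * (2 / 3) / length(firsts))
  expect_true(all(abs(freq - 1 / 3) < 3 * se))

  # asymmetric chain: planted marginals approach the eigen-stationary law
  A <- matrix(c(0.8, 0.15, 0.05,
                0.1, 0.8, 0.1,
                0.05, 0.15, 0.8), 3, 3, byrow = TRUE)
  spec2 <- cohort_spec(n_patients = 2, n_genes = 30000, n_chromosomes = 10,
                       hmm_truth = hmm_params(A = A, sigma2 = rep(1, 3)),
                       seed = 3,
                       signature_truth = list(effect = 0, class_effect = 0,
                                              gcimp_effect = 0,
                                              n_subgroup_genes = 2,
                                              n_class_genes = 2,
                                              n_gcimp_genes = 2))
  pf2 <- simulate_pair_profiles(spec2)
  ev <- eigen(t(A))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  emp <- table(factor(pf2$states, levels = -1:1)) / length(pf2$states)
  expect_true(all(abs(emp - stat) < 0.02))
})

test_that("variant tables plant exactly the requested pair structure", {
  # forced: only shared variants -> identical call sets
  vt <- data.frame(patient = c("P01", "P02"), shared = c(8, 60),
                   initial_private = c(0, 26), recurrent_private = c(0, 77))
  spec <- small_spec(n_patients = 2, variant_truth = vt)
  vars <- simulate_variant_tables(spec)
  p1 <- vars$pairs$P01
  expect_equal(nrow(p1$initial), 8)
  k <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
  expect_setequal(k(p1$initial), k(p1$recurrent))

  # round-trip of planted counts through shared_private
  expect_equal(unname(shared_private(vars$pairs$P02$initial,
                                     vars$pairs$P02$recurrent)),
               c(60, 26, 77))

  # disjoint per-pair position ranges: no cross-pair key collisions
  keys <- unlist(lapply(vars$pairs, function(p) unique(c(k(p$initial), k(p$recurrent)))))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(n_genes = 5, n_chromosomes = 10), "invalid spec")
  expect_error(small_spec(noise_sd = 0), "noise_sd")
  bad_A <- matrix(c(0.5, 0.5, 0.5, 0.05, 0.9, 0.05, 0.05, 0.05, 0.9),
                  3, 3, byrow = TRUE)
  expect_error(hmm_params(A = bad_A), "row-stochastic")
  expect_error(hmm_params(mu = c(0, -3, 3)), "increasing")
})
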