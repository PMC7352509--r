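mk_labels <- function(m, genes, pairs) {
  matrix(m, length(genes), length(pairs), dimnames = list(genes, pairs))
}

test_that("alteration counts tally decoded labels per group", {
  genes <- paste0("g", 1:4)
  labels <- mk_labels(0L, genes, c("P1", "P2", "P3"))
  labels["g1", "P1"] <- 1L
  labels["g2", c("P1", "P2")] <- -1L
  labels["g3", "P3"] <- 1L
  groups <- list("A2->A3" = c("P1", "P2"), "A3->G4" = "P3")
  cnt <- group_alteration_counts(labels, groups)
  expect_equal(cnt[["A2->A3"]]$n_over, c(1, 0, 0, 0))
  expect_equal(cnt[["A2->A3"]]$n_under, c(0, 2, 0, 0))
  expect_equal(cnt[["A3->G4"]]$n_over, c(0, 0, 1, 0))
  # conservation: total counted labels equals total non-zero calls
  total <- sum(vapply(cnt, function(s) sum(s$n_under + s$n_over), numeric(1)))
  expect_equal(total, sum(labels != 0))
  expect_error(group_alteration_counts(labels, list(empty = character(0))),
               "zero pairs")
  expect_error(group_alteration_counts(labels, list(g = "P9")), "no decoding")
})

test_that("seeded decoding tallies match a brute-force count", {
  spec <- small_spec(n_patients = 6)
  pf <- simulate_pair_profiles(spec)
  dec <- posterior_decode(pf, spec$hmm_truth)
  groups <- list(grp = pf$patients)
  cnt <- group_alteration_counts(dec, groups)$grp
  for (i in sample(nrow(pf$values), 25)) {
    expect_equal(cnt$n_under[i], sum(dec$labels[i, ] == -1))
    expect_equal(cnt$n_over[i], sum(dec$labels[i, ] == 1))
  }
})

test_that("frequent sets include the exact-50% boundary", {
  genes <- paste0("g", 1:3)
  s <- list(G = data.frame(gene = genes,
                           n_under = c(3, 0, 0), n_over = c(0, 2, 4),
                           n_pairs = c(6, 5, 6)))
  fs <- frequent_sets(s, min_fraction = 0.5)
  expect_equal(fs$sets$G$under, "g1")   # 3/6 = 50% -> included
  expect_equal(fs$sets$G$over, "g3")    # 2/5 = 40% -> excluded
  expect_error(frequent_sets(s, min_fraction = 0), "min_fraction")

  # a gene cannot be under and over in one group when min_fraction > 0.5,
  # but can sit in both sets at exactly 0.5
  both <- list(G = data.frame(gene = "g", n_under = 2, n_over = 2, n_pairs = 4))
  fs_half <- frequent_sets(both, 0.5)
  expect_true("g" %in% fs_half$sets$G$under && "g" %in% fs_half$sets$G$over)
  fs_60 <- frequent_sets(both, 0.6)
  expect_false("g" %in% fs_60$sets$G$under || "g" %in% fs_60$sets$G$over)

  # lower thresholds give supersets; epsilon threshold equals ">= 1 pair"
  spec <- small_spec(n_patients = 6)
  pf <- simulate_pair_profiles(spec)
  dec <- posterior_decode(pf, spec$hmm_truth)
  groups <- list(a = pf$patients[1:3], b = pf$patients[4:6])
  cnt <- group_alteration_counts(dec, groups)
  f_lo <- frequent_sets(cnt, 1e-9)
  f_mid <- frequent_sets(cnt, 0.5)
  f_hi <- frequent_sets(cnt, 1)
  for (g in names(groups)) {
    for (dir in c("under", "over")) {
      expect_true(all(f_hi$sets[[g]][[dir]] %in% f_mid$sets[[g]][[dir]]))
      expect_true(all(f_mid$sets[[g]][[dir]] %in% f_lo$sets[[g]][[dir]]))
      atleast1 <- cnt[[g]]$gene[cnt[[g]][[paste0("n_", dir)]] >= 1]
      expect_setequal(f_lo$sets[[g]][[dir]], atleast1)
    }
  }
})

test_that("cross-group Venn regions equal a set-algebra oracle", {
  mk <- function(u, o) data.frame(gene = paste0("g", 1:10),
                                  n_under = ifelse(paste0("g", 1:10) %in% u, 2, 0),
                                  n_over = ifelse(paste0("g", 1:10) %in% o, 2, 0),
                                  n_pairs = 2)
  s <- list(A = mk(c("g1", "g2", "g3"), c("g7")),
            B = mk(c("g2", "g3", "g4"), c("g7", "g8")),
            C = mk(c("g3", "g5"), character(0)))
  fs <- frequent_sets(s, 0.5)
  v <- fs$venn$under
  expect_equal(unname(v[["A"]]), 1)        # g1
  expect_equal(unname(v[["A+B"]]), 1)      # g2
  expect_equal(unname(v[["A+B+C"]]), 1)    # g3
  expect_equal(unname(v[["B"]]), 1)        # g4
  expect_equal(unname(v[["C"]]), 1)        # g5
  expect_equal(sum(v), length(unique(c("g1", "g2", "g3", "g4", "g5"))))
  expect_equal(unname(fs$venn$over[["A+B"]]), 1)  # g7
  # opposite-direction overlap: A.under vs B.over etc are empty here
  expect_true(all(fs$opposite == 0))

  s2 <- list(A = mk("g1", "g9"), B = mk("g9", "g1"))
  fs2 <- frequent_sets(s2, 0.5)
  expect_equal(unname(fs2$opposite[["A.under+B.over"]]), 1)
  expect_equal(unname(fs2$opposite[["B.under+A.over"]]), 1)
})

test_that("average alteration profiles mean over contributing pairs only", {
  genes <- paste0("g", 1:3)
  vals <- matrix(c(2, -1, 0,
                   4, -3, 0), 3, 2, dimnames = list(genes, c("P1", "P2")))
  labels <- matrix(c(1L, -1L, 0L,
                     1L, 0L, 0L), 3, 2, dimnames = list(genes, c("P1", "P2")))
  pf <- structure(list(values = vals, gene_map = NULL), class = "pair_profiles")
  dec <- structure(list(labels = labels), class = "posterior_decoding")
  over <- average_alteration_profile(pf, dec, c("P1", "P2"), "over")
  expect_equal(over$gene, "g1")
  expect_equal(over$mean_logratio, 3)      # (2 + 4) / 2
  expect_equal(over$n_pairs, 2)
  under <- average_alteration_profile(pf, dec, c("P1", "P2"), "under")
  expect_equal(under$gene, "g2")
  expect_equal(under$mean_logratio, -1)    # single contributing pair
  # restricting to a gene list drops everything else
  none <- average_alteration_profile(pf, dec, c("P1", "P2"), "over",
                                     genes = "g3")
  expect_equal(nrow(none), 0)
})

test_that("alteration directions have consistent signs on planted data", {
  spec <- small_spec(n_patients = 6,
                     hmm_truth = hmm_params(sigma2 = rep(1e-6, 3)))
  pf <- simulate_pair_profiles(spec)
  dec <- posterior_decode(pf, spec$hmm_truth)
  groups <- list(all = pf$patients)
  under <- average_alteration_profile(pf, dec, pf$patients, "under")
  over <- average_alteration_profile(pf, dec, pf$patients, "over")
  expect_true(all(under$mean_logratio < 0))
  expect_true(all(over$mean_logratio > 0))
})

test_that("pathway profiles report per-pathway altered proportions", {
  s <- list(G = data.frame(gene = paste0("g", 1:10),
                           n_under = c(rep(2, 2), rep(0, 8)),
                           n_over = c(0, 0, 2, 2, 2, rep(0, 5)),
                           n_pairs = 2))
  fs <- frequent_sets(s, 0.5)
  annot <- list(pwA = paste0("g", 3:5),    # fully inside the over-set
                pwB = paste0("g", 6:8),    # disjoint from both sets
                pwC = paste0("g", 1:4))    # mixed
  pw <- pathway_alteration_profile(fs, annot, paste0("g", 1:10))
  get <- function(p, d) pw$proportion[pw$pathway == p & pw$direction == d]
  expect_equal(get("pwA", "over"), 1)
  expect_equal(get("pwB", "over"), 0)
  expect_equal(get("pwB", "under"), 0)
  expect_equal(get("pwC", "under"), 2 / 4)
  expect_equal(get("pwC", "over"), 2 / 4)
})
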