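test_that("correlation distance matches the direct formula", {
  X <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  D <- corr_distance(X)
  expect_equal(D["a", "b"], 0)           # identical up to positive scale
  expect_equal(D["a", "c"], 2)           # exactly anti-correlated
  expect_equal(diag(D), setNames(rep(0, 3), rownames(X)))

  set.seed(4)
  Y <- matrix(rnorm(50), 5, 10)
  DY <- corr_distance(Y)
  for (i in 1:4) for (j in (i + 1):5) {
    r <- sum((Y[i, ] - mean(Y[i, ])) * (Y[j, ] - mean(Y[j, ]))) /
      ((10 - 1) * sd(Y[i, ]) * sd(Y[j, ]))
    expect_equal(DY[i, j], 1 - r, tolerance = 1e-12)
  }

  # invariant under positive affine transforms of a sample
  Y2 <- Y; Y2[2, ] <- 3 * Y[2, ] + 7
  expect_equal(corr_distance(Y2), DY, tolerance = 1e-12)

  Yc <- Y; Yc[3, ] <- 5
  expect_error(corr_distance(Yc), "constant sample")
})

test_that("ward.D2 trees equal the naive Lance-Williams oracle (n <= 6)", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    X <- matrix(rnorm(n * 8), n, 8, dimnames = list(paste0("s", 1:n), NULL))
    D <- corr_distance(X)
    tree <- ward_tree(D)
    oracle <- oracle_ward(D)
    expect_equal(sort(tree$height), oracle$heights, tolerance = 1e-10)
    expect_identical(hclust_node_sets(tree), oracle$node_sets)
  }
})

test_that("ward tree basics: forced merges and symmetry checks", {
  # two samples: one merge at their distance
  X <- rbind(a = c(0, 1, 2), b = c(2, 1, 0))
  D <- corr_distance(X)
  tr <- ward_tree(D)
  expect_equal(tr$height, D["a", "b"])

  # duplicated sample merges first at height 0
  Y <- rbind(a = c(1, 3, 2, 5), b = c(1, 3, 2, 5), c = c(9, 1, 4, 2))
  tr2 <- ward_tree(corr_distance(Y))
  expect_equal(min(tr2$height), 0)
  expect_identical(sort(node_sets <- hclust_node_sets(tr2))[1], "a|b")

  Dbad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ward_tree(Dbad), "symmetric")
})

test_that("k-cuts are exact and recover planted subgroups", {
  co <- simulate_cohort(small_spec(n_patients = 9))
  tum <- co$samples$sample_id[co$samples$stage != "normal"]
  tree <- ward_tree(corr_distance(t(co$expr[, tum])))
  expect_equal(length(unique(cut_major_clusters(tree, 1))), 1)
  expect_equal(length(unique(cut_major_clusters(tree, length(tum)))),
               length(tum))
  expect_error(cut_major_clusters(tree, length(tum) + 1), "k must be")

  cl <- cut_major_clusters(tree, 3)
  expect_true(perfect_partition_match(cl, co$truth$subgroup[tum]))
})

test_that("matched-pair adjacency distinguishes direct, same and different", {
  # duplicated pair profiles cluster directly together
  X <- rbind("P1-I" = c(1, 5, 2, 4), "P1-R" = c(1, 5, 2, 4),
             "P2-I" = c(9, 1, 4, 2), "P2-R" = c(8, 2, 4, 1))
  tree <- ward_tree(corr_distance(X))
  pairs <- data.frame(patient = c("P1", "P2"),
                      initial = c("P1-I", "P2-I"),
                      recurrent = c("P1-R", "P2-R"))
  adj <- matched_pair_adjacency(tree, pairs, k = 2)
  expect_equal(adj$status[adj$patient == "P1"], "direct")
  expect_error(matched_pair_adjacency(tree, data.frame(
    patient = "P9", initial = "nope", recurrent = "P1-R")), "unknown sample")

  # an n = 2 cohort's only pair is direct
  tree2 <- ward_tree(corr_distance(X[1:2, ] + matrix(rnorm(8, 0, 0.1), 2)))
  adj2 <- matched_pair_adjacency(tree2, pairs[1, ], k = 1)
  expect_equal(adj2$status, "direct")

  # pairs planted in different subgroups end up in different clusters at k=3
  co <- simulate_cohort(small_spec(n_patients = 9))
  tum <- co$samples$sample_id[co$samples$stage != "normal"]
  tree3 <- ward_tree(corr_distance(t(co$expr[, tum])))
  sheet <- co$samples[co$samples$stage != "normal", ]
  pr <- data.frame(patient = unique(sheet$patient))
  pr$initial <- paste0(pr$patient, "-I")
  pr$recurrent <- paste0(pr$patient, "-R")
  adj3 <- matched_pair_adjacency(tree3, pr, k = 3)
  sg <- co$truth$subgroup
  discordant <- pr$patient[sg[pr$initial] != sg[pr$recurrent]]
  expect_true(length(discordant) > 0)
  expect_true(all(adj3$status[adj3$patient %in% discordant] == "different-cluster"))
})

test_that("bootstrap support is high for well-separated planted clusters", {
  set.seed(6)
  # opposite feature patterns: high within-group, negative between-group
  # correlation (a constant offset would be invisible to Pearson distance)
  pattern <- sample(c(-2, 2), 60, replace = TRUE)
  X <- rbind(matrix(rep(pattern, each = 5), 5, 60) + rnorm(300, 0, 0.5),
             matrix(rep(-pattern, each = 5), 5, 60) + rnorm(300, 0, 0.5))
  rownames(X) <- paste0("s", 1:10)
  tree <- ward_tree(corr_distance(X))
  supp <- bootstrap_support(X, tree, B = 100, seed = 1)
  expect_true(all(supp >= 0 & supp <= 1))

  sets <- hclust_node_sets(tree)
  g1 <- paste(sort(paste0("s", 1:5)), collapse = "|")
  g2 <- paste(sort(paste0("s", 6:10)), collapse = "|")
  node_order <- vapply(astropair:::node_leaf_sets(tree), paste, character(1),
                       collapse = "|")
  expect_gte(supp[match(g1, node_order)], 0.95)
  expect_gte(supp[match(g2, node_order)], 0.95)

  # B = 1 yields only 0/1 supports
  s1 <- bootstrap_support(X, tree, B = 1, seed = 3)
  expect_true(all(s1 %in% c(0, 1)))

  # conclusions are stable under feature reordering
  perm <- sample(ncol(X))
  supp_perm <- bootstrap_support(X[, perm], tree, B = 100, seed = 2)
  expect_gte(supp_perm[match(g1, node_order)], 0.95)
  expect_gte(supp_perm[match(g2, node_order)], 0.95)
})
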