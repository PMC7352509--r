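#!/usr/bin/env Rscript
# Stage 4: unsupervised structure of the tumor expression profiles.
#
# Clusters the normalized tumor transcriptomes (1 - Pearson, ward.D2), cuts
# three major subclusters, asks which patient-matched pairs cluster
# directly together, and bootstraps subcluster stability.

library(astropair)
SEED <- 1
DATA <- "results/data"
OUT <- "results/expression_clustering"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

norm <- read_tsv(file.path(DATA, "expression_normalized.tsv"), row_col = "gene")
sheet <- read_tsv(file.path(DATA, "samples.tsv"))
tumors <- sheet$sample_id[sheet$stage != "normal"]

X <- t(norm[, tumors])
tree <- ward_tree(corr_distance(X))
cl <- cut_major_clusters(tree, 3)
write_tsv(data.frame(sample = names(cl), cluster = cl),
          file.path(OUT, "clusters.tsv"))

pairs <- data.frame(patient = unique(sheet$patient[sheet$stage != "normal"]))
pairs$initial <- paste0(pairs$patient, "-I")
pairs$recurrent <- paste0(pairs$patient, "-R")
adj <- matched_pair_adjacency(tree, pairs, k = 3)
write_tsv(adj, file.path(OUT, "pair_adjacency.tsv"))

supp <- bootstrap_support(X, tree, B = 100, seed = SEED)
write_tsv(data.frame(node = seq_along(supp), support = supp),
          file.path(OUT, "bootstrap_support.tsv"))

cat(sprintf("Cluster sizes at k=3: %s\n", paste(table(cl), collapse = " / ")))
cat(sprintf("Pairs clustering directly together: %d/%d (%.1f%%)\n",
            sum(adj$status == "direct"), nrow(adj),
            100 * mean(adj$status == "direct")))
cat(sprintf("Pairs split across different major clusters: %d/%d\n",
            sum(adj$status == "different-cluster"), nrow(adj)))
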