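#!/usr/bin/env Rscript
# Stage 8: progression-group aggregation of per-pair state calls.
#
# Counts under/over calls per gene within each WHO-grade progression group,
# restricts to genes altered in at least 50% of a group's pairs, compares
# the groups by Venn partition, and builds average alteration and pathway
# profiles of the frequent genes.

library(astropair)
SEED <- 1
DATA <- "results/data"
OUT <- "results/progression"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

sheet <- read_tsv(file.path(DATA, "samples.tsv"))
gm <- read_tsv(file.path(DATA, "gene_map.tsv"))
class(gm) <- c("gene_map", "data.frame")
vals <- read_tsv(file.path(DATA, "pair_logratio_profiles.tsv"), row_col = "gene")
dec_df <- read_tsv("results/hmm/decoding.tsv")
labels <- matrix(dec_df$label, nrow(vals),
                 dimnames = list(unique(dec_df$gene), unique(dec_df$patient)))

groups <- progression_groups(sheet)
counts <- group_alteration_counts(labels, groups)
freq <- frequent_sets(counts, min_fraction = 0.5)
jsonlite::write_json(freq$venn, file.path(OUT, "venn.json"),
                     auto_unbox = TRUE, digits = NA)

profiles <- structure(list(values = vals, gene_map = gm),
                      class = "pair_profiles")
decoding <- structure(list(labels = labels), class = "posterior_decoding")
for (g in names(freq$sets)) {
  tag <- gsub("[^A-Za-z0-9]", "", g)
  for (dir in c("under", "over")) {
    writeLines(freq$sets[[g]][[dir]],
               file.path(OUT, sprintf("frequent_%s_%s.txt", tag, dir)))
    prof <- average_alteration_profile(profiles, decoding, groups[[g]],
                                       direction = dir,
                                       genes = freq$sets[[g]][[dir]])
    write_tsv(prof, file.path(OUT, sprintf("profile_%s_%s.tsv", tag, dir)))
  }
  cat(sprintf("%s (%d pairs): %d under-, %d overexpressed genes in >= 50%% of pairs\n",
              g, length(groups[[g]]), length(freq$sets[[g]]$under),
              length(freq$sets[[g]]$over)))
}
cat(sprintf("Genes frequently altered in the same direction in all three groups: %d (under), %d (over)\n",
            unname(freq$venn$under[paste(names(groups), collapse = "+")]),
            unname(freq$venn$over[paste(names(groups), collapse = "+")])))

annot <- simulate_annotations(gm, seed = SEED)
pw <- pathway_alteration_profile(freq, annot, rownames(vals))
write_tsv(pw, file.path(OUT, "pathways.tsv"))
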