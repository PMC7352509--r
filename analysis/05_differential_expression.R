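#!/usr/bin/env Rscript
# Stage 5: cluster-vs-normal differential expression.
#
# For each major expression cluster, a moderated two-group test against the
# normal brain references; genes at q <= 0.01 are split into under- and
# overexpressed sets, compared across clusters by Venn partition, and
# checked for overrepresented annotation categories by one-sided Fisher
# tests. The IDH1-mutant vs wild-type contrast reuses the same machinery.

library(astropair)
SEED <- 1
DATA <- "results/data"
OUT <- "results/differential_expression"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

norm <- read_tsv(file.path(DATA, "expression_normalized.tsv"), row_col = "gene")
sheet <- read_tsv(file.path(DATA, "samples.tsv"))
cl <- read_tsv("results/expression_clustering/clusters.tsv")
normals <- sheet$sample_id[sheet$stage == "normal"]

gm <- read_tsv(file.path(DATA, "gene_map.tsv"))
class(gm) <- c("gene_map", "data.frame")
annot <- simulate_annotations(gm, seed = SEED)
write_gmt(annot, file.path(OUT, "annotations.gmt"))

de <- lapply(sort(unique(cl$cluster)), function(k) {
  moderated_two_group_test(norm, cl$sample[cl$cluster == k], normals,
                           q_cut = 0.01)
})
names(de) <- paste0("cluster", sort(unique(cl$cluster)))
for (nm in names(de)) write_tsv(de[[nm]], file.path(OUT, paste0(nm, ".tsv")))

vd <- de_sets_and_venn(de, threshold = 0.01)
jsonlite::write_json(vd$venn, file.path(OUT, "venn.json"),
                     auto_unbox = TRUE, digits = NA)
enr <- do.call(rbind, lapply(names(de), function(nm) {
  do.call(rbind, lapply(c("under", "over"), function(dir) {
    e <- category_enrichment(vd$sets[[nm]][[dir]], rownames(norm), annot)
    e$cluster <- nm; e$direction <- dir
    e
  }))
}))
write_tsv(enr, file.path(OUT, "enrichment.tsv"))

for (nm in names(de)) {
  cat(sprintf("%s vs normal: %d under-, %d overexpressed genes (q <= 0.01)\n",
              nm, length(vd$sets[[nm]]$under), length(vd$sets[[nm]]$over)))
}

# IDH1-mutant vs wild type, tumors only
mut <- sheet$sample_id[sheet$stage != "normal" & sheet$idh1 == "mut"]
wt <- sheet$sample_id[sheet$stage != "normal" & sheet$idh1 == "wt"]
idh <- moderated_two_group_test(norm, mut, wt, q_cut = 0.01)
write_tsv(idh, file.path(OUT, "idh1_mut_vs_wt.tsv"))
cat(sprintf("IDH1 mut vs wt: %d under-, %d overexpressed genes (q <= 0.01)\n",
            sum(idh$direction == "under"), sum(idh$direction == "over")))
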