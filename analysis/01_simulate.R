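#!/usr/bin/env Rscript
# Stage 1: simulate the patient-matched astrocytoma cohort.
#
# Generates the synthetic cohort the whole analysis runs on: 21 tumor pairs
# (A2->A3: 6, A2->G4: 5, A3->G4: 10) plus 4 normal brain references over a
# 2000-gene genome, with planted copy-number subgroups, expression
# subgroups, subtype centroids, HMM expression-state runs and paired
# somatic variants. All downstream stages read what this stage writes.

library(astropair)
SEED <- 1
DATA <- "results/data"
dir.create(file.path(DATA, "vcf"), showWarnings = FALSE, recursive = TRUE)

spec <- cohort_spec(seed = SEED)
print(spec)

cohort <- simulate_cohort(spec)
write_tsv(cohort$expr, file.path(DATA, "expression_log2.tsv"), id_col = "gene")
counts <- matrix(
  astropair:::with_substream(SEED, "counts",
    rpois(length(cohort$expr), pmax(2^cohort$expr, 1e-8))),
  nrow = nrow(cohort$expr), dimnames = dimnames(cohort$expr))
write_tsv(counts, file.path(DATA, "counts.tsv"), id_col = "gene")
write_seg(cohort$segments, file.path(DATA, "segments.seg"))
write_tsv(cohort$samples, file.path(DATA, "samples.tsv"))
write_tsv(cohort$gene_map, file.path(DATA, "gene_map.tsv"))
write_signature_gmt(cohort$signatures, file.path(DATA, "subtype_signatures.gmt"))
write_signature_gmt(list(GCIMP = cohort$gcimp_signature),
                    file.path(DATA, "gcimp_signature.gmt"))
write_tsv(data.frame(sample = names(cohort$truth$subgroup),
                     subgroup = cohort$truth$subgroup,
                     subtype = cohort$truth$subtype,
                     gcimp = cohort$truth$gcimp),
          file.path(DATA, "truth_samples.tsv"))

profiles <- simulate_pair_profiles(spec, gene_map = cohort$gene_map)
write_tsv(profiles$values, file.path(DATA, "pair_logratio_profiles.tsv"),
          id_col = "gene")
write_tsv(profiles$states, file.path(DATA, "truth_pair_states.tsv"),
          id_col = "gene")

vars <- simulate_variant_tables(spec, gene_map = cohort$gene_map)
for (p in vars$pairs) {
  write_vcf(p$initial, file.path(DATA, "vcf", paste0(p$patient, "-I.vcf")))
  write_vcf(p$recurrent, file.path(DATA, "vcf", paste0(p$patient, "-R.vcf")))
}
write_tsv(vars$truth, file.path(DATA, "truth_variants.tsv"))

sheet <- cohort$samples
cat(sprintf("\nWrote cohort: %d tumor samples (%d pairs) + %d normals, %d genes.\n",
            sum(sheet$stage != "normal"), spec$n_patients,
            sum(sheet$stage == "normal"), spec$n_genes))
cat("Progression groups:\n")
print(table(sheet$group[sheet$stage == "initial"]))
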