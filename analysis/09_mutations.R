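#!/usr/bin/env Rscript
# Stage 9: somatic variant summaries of the matched pairs.
#
# Reads the per-sample VCFs, partitions each pair's SNVs into shared /
# initial-private / recurrent-private, tallies functional classes, and
# ranks genes by the fraction of pairs carrying mutations, overall and per
# progression group, under both sharing semantics.

library(astropair)
DATA <- "results/data"
OUT <- "results/mutations"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

sheet <- read_tsv(file.path(DATA, "samples.tsv"))
patients <- unique(sheet$patient[sheet$stage != "normal"])
pairs <- lapply(patients, function(pid) {
  list(initial = read_vcf_variants(
         file.path(DATA, "vcf", paste0(pid, "-I.vcf")), sample = paste0(pid, "-I")),
       recurrent = read_vcf_variants(
         file.path(DATA, "vcf", paste0(pid, "-R.vcf")), sample = paste0(pid, "-R")))
})
names(pairs) <- patients

sp <- t(vapply(pairs, function(p) shared_private(p$initial, p$recurrent),
               numeric(3)))
write_tsv(data.frame(patient = rownames(sp), sp),
          file.path(OUT, "shared_private.tsv"))
cat(sprintf("Shared SNVs per pair: %d-%d (mean %.0f); private: initial mean %.0f, recurrent mean %.0f\n",
            min(sp[, "shared"]), max(sp[, "shared"]), mean(sp[, "shared"]),
            mean(sp[, "initial_private"]), mean(sp[, "recurrent_private"])))

tallies <- do.call(rbind, lapply(patients, function(pid) {
  rbind(data.frame(sample = paste0(pid, "-I"),
                   t(functional_tally(pairs[[pid]]$initial))),
        data.frame(sample = paste0(pid, "-R"),
                   t(functional_tally(pairs[[pid]]$recurrent))))
}))
write_tsv(tallies, file.path(OUT, "functional_tally.tsv"))
cat(sprintf("Mean nonsynonymous SNVs per tumor: %.1f; mean intronic: %.1f\n",
            mean(tallies$nonsynonymous), mean(tallies$intronic)))

groups <- progression_groups(sheet)
for (scope in c("shared-in-pair", "any-sample")) {
  tag <- gsub("[^a-z]", "_", scope)
  gf <- gene_frequency(pairs, scope = scope)
  write_tsv(head(gf, 50), file.path(OUT, paste0("gene_frequency_", tag, ".tsv")))
  gfg <- gene_frequency(pairs, scope = scope, groups = groups)
  write_tsv(do.call(rbind, lapply(split(gfg, gfg$group), head, 20)),
            file.path(OUT, paste0("gene_frequency_", tag, "_by_group.tsv")))
  cat(sprintf("Top genes (%s): %s\n", scope,
              paste(sprintf("%s %.0f%%", head(gf$gene, 3),
                            100 * head(gf$frequency, 3)), collapse = ", ")))
}
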