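# astropair

Analysis of patient-matched astrocytoma pairs — an initial tumor and its
recurrence from the same patient — through progression to secondary
glioblastoma. The package implements the full desk side of such a study:

* gene-level copy-number profiles from segmented aCGH data, Ward
  (`ward.D2`) clustering on one-minus-Pearson distances, bootstrap
  subcluster stability, and whole-chromosome/arm loss–gain calls;
* moderated differential expression of tumor clusters against normal brain
  references (empirical-Bayes variance moderation, BH-FDR at q ≤ 0.01),
  Venn comparisons and Fisher category enrichment;
* G-CIMP and four-class (proneural / neural / classical / mesenchymal)
  subtyping by centroid correlation on tumor-vs-normal log-ratios, with
  initial→recurrent transition tables;
* the core method: a **three-state first-order Gaussian HMM** over
  chromosomally ordered per-pair log2(recurrent/initial) expression
  ratios, trained by pooled Baum–Welch across all pairs and decoded per
  gene into underexpressed / unchanged / overexpressed states;
* aggregation of per-pair state calls into progression groups (A2→A3,
  A2→G4, A3→G4) with the inclusive ≥ 50%-of-pairs frequent-set rule; and
* shared/private somatic SNV summaries and gene mutation frequencies for
  matched pairs.

Real cohorts of this design are institutional; the package therefore ships
a deterministic synthetic-cohort generator with planted ground truth
(copy-number subgroups, expression subgroups, subtype centroids, HMM state
paths, paired variant sets), so every stage is testable end to end.

## The model at the core

For patient *p*, let `x_pg = log2 e_rec,g − log2 e_init,g` be the expression
log-ratio of gene *g*, with genes in chromosomal order. Each chromosome is
an independent sequence of a first-order HMM with hidden states
`k ∈ {under, unchanged, over}`, initial distribution π, transition matrix A,
and Gaussian emissions `x | k ~ N(μ_k, σ²_k)` with `μ_under < μ_unchanged <
μ_over` (initialized at −3, 0, 3). One model is trained on all pairs by
multi-sequence Baum–Welch (log-space forward–backward in compiled code),
and each gene is assigned its maximum-posterior state. Runs of shared state
along a chromosome are exactly the dosage footprints of segmental copy
number changes that motivate the model.

## Worked example

Simulate the default cohort (21 pairs split 6/5/10 across the progression
groups, 4 normal references, 2,000 genes), train the HMM and decode:

```r
library(astropair)

spec <- cohort_spec(seed = 1)
profiles <- simulate_pair_profiles(spec)   # planted paths in profiles$states

fit <- fit_hmm(profiles, init = hmm_params())
print(fit$params)
#> 3-state Gaussian HMM parameters
#>   pi:     0.3088  0.3715  0.3197
#>   mu:     -2.996  0.001421  2.994
#>   sigma:  0.699  0.6994  0.6991
#>   A:
#>         [,1]    [,2]    [,3]
#> [1,] 0.89820 0.05244 0.04937
#> [2,] 0.04854 0.90420 0.04724
#> [3,] 0.05070 0.05025 0.89910

decoding <- posterior_decode(profiles, fit$params)
mean(decoding$labels == profiles$states)
#> [1] 0.9966667
```

The fitted means sit at the planted (−3, 0, 3), the transition diagonal at
the planted 0.9, and 99.7% of per-gene states are decoded correctly.
Aggregating the calls over progression groups and applying the ≥ 50% rule:

```r
cohort <- simulate_cohort(spec)
groups <- progression_groups(cohort$samples)
counts <- group_alteration_counts(decoding, groups)
freq <- frequent_sets(counts, min_fraction = 0.5)
lengths(freq$sets[["A2->A3"]])
#> under  over
#>   604   578
```

`run_pipeline(out = "results/pipeline", seed = 1)` executes every stage in
order (simulation, preprocessing, copy number, clustering, differential
expression, HMM, subtyping, progression, mutations) and writes plain-text
artifacts plus a checksummed manifest; re-running with the same seed
reproduces the manifest byte for byte.

The numbered scripts under `analysis/` run the same stages as a readable
narrative (`Rscript analysis/01_simulate.R`, then `02` … `09`), writing
their tables under `results/`. Highlights of the seed-1 run: the three
planted subgroups are recovered exactly by both copy-number and expression
clustering; the planted chromosome-10 deletion is called in 21/21 recurrent
and 0/21 initial tumors; 6/21 pairs cluster directly together; all 7
initial proneural tumors recur as mesenchymal; the top shared-in-pair
mutated genes are the planted drivers at 71% and 62% of pairs.

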