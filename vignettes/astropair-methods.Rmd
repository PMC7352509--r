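---
title: "Methods: patient-matched astrocytoma progression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-matched astrocytoma progression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`astropair` analyzes cohorts of patient-matched tumor pairs — an initial
astrocytoma and its recurrence from the same patient — through a fixed
sequence of stages: gene-level copy-number profiling and clustering,
cluster-versus-normal differential expression, molecular subtyping by
centroid correlation, per-pair expression-state calling with a three-state
Gaussian hidden Markov model (HMM), aggregation of those calls over
WHO-grade progression groups (A2→A3, A2→G4, A3→G4), and shared/private
somatic-variant summaries. Because real patient-matched cohorts of this
kind are institutional and not publicly deposited, the package ships a
synthetic-cohort generator with planted ground truth; every stage is
validated against that truth or against independent oracles.

# The expression-state HMM

The core method treats the per-gene log2 expression ratio of a recurrent
versus its initial tumor, ordered along the chromosomes, as the observation
sequence of a first-order HMM with three hidden states: underexpressed,
unchanged, and overexpressed in the recurrence. The motivation is that
deletions and duplications of DNA segments shift the expression of *runs*
of neighboring genes coherently, so state calls should borrow strength
along the chromosome instead of thresholding each gene separately.

* Emissions are state-specific normal densities `N(mu_k, sigma2_k)` on the
  log2 ratio; means are initialized at −3, 0, and 3 log2 units and the
  ordering `mu_under < mu_unchanged < mu_over` is maintained throughout
  training by relabeling states after each M-step.
* One model is trained on **all** pairs jointly (pooled Baum–Welch:
  expected counts from every profile and chromosome are summed before each
  M-step). Per-profile training is a flag away but not the default; the
  cohort-level model is what the progression-group aggregation consumes.
* Chromosomes are independent sequences, each restarting from the initial
  distribution `pi`. The dependency being modeled is local chromosomal
  proximity, which does not carry across chromosome ends;
  `concat_genome = TRUE` chains a whole profile instead.
* All of `pi`, the transition matrix `A`, `mu` and `sigma2` are
  re-estimated by default (`estimate_pi`, `estimate_A`, `tie_variances`
  switch this). Initialization beyond the means: uniform `pi`, 0.9
  self-transitions, unit variances.
* Numerics: the forward, backward and posterior recursions run in log
  space (log-sum-exp) in compiled code; EM stops when the total
  log-likelihood gain drops below `tol = 1e-4` or at `max_iter = 200`;
  emission variances are clamped at `1e-4` (with a warning) to prevent
  collapse on degenerate data, and states that lose all posterior mass
  retain their previous parameters rather than producing NaNs.
* Decoding is by maximum posterior state per gene (forward–backward, not
  Viterbi), with ties resolved toward `unchanged` — the conservative call.

On 25 simulated profiles of 2,000 genes drawn from the generating model
(`mu = (−3, 0, 3)`, `sigma = 0.7`, self-transitions 0.9), pooled training
recovers the means within a few 10⁻³ log2 units, the transition diagonal
within ~0.005, and decoded states match the planted paths at ≈ 99.6%;
the test suite asserts the looser bounds ±0.15, ±0.03 and ≥ 95%.

# Copy-number and clustering stages

Copy-number segments (SEG-style, 1-based inclusive on disk, converted to
0-based half-open internally) are mapped to genes by **midpoint
containment**: each gene takes the mean log2-ratio of the segment containing
its midpoint. This is deterministic, order-independent, and agrees with an
exhaustive overlap scan in the tests; overlap-weighted averaging was
deliberately not used because segment boundaries inside a gene are rare and
the simpler rule is reproducible.

Sample clustering uses one minus Pearson correlation as distance with
Ward's method in the `ward.D2` dialect (squared dissimilarities inside the
Lance–Williams recurrence). The implementation delegates to `stats::hclust`;
an independent naive Lance–Williams oracle in the test suite confirms
heights and topology for all small instances. Note that a constant offset
between samples is invisible to correlation distance — group structure must
live in feature *patterns*, which is how the generator plants it.

Subcluster stability is a plain feature bootstrap: features are resampled
with replacement, the tree is rebuilt, and a node's support is the fraction
of replicate trees containing exactly its leaf set (bootstrap probability,
BP). The multiscale AU correction of the original stability software is
intentionally omitted: BP is sufficient to separate stable planted
subclusters (support 1.0 on copy-number profiles) from incidental nodes.
A pair "clusters directly together" when some internal node's leaf set is
exactly the two samples of that pair.

Chromosome/arm event calls use thresholds `loss_cut = −0.3`,
`gain_cut = 0.3` and `min_fraction = 0.7` of the scope's genes — conventional
aCGH practice; the cohorts these methods target report such events
qualitatively, so the thresholds are package choices and are configurable.
When both directions qualify, the larger fraction wins and exact ties are
neutral.

# Differential expression and enrichment

The cluster-versus-normal (and IDH1-mutant versus wild-type) contrast is a
two-sample test with empirical-Bayes variance moderation: per-gene pooled
variances `s²` on `d` degrees of freedom are shrunk toward a prior
`(d0, s0²)` fitted across genes by the method of moments on `log s²`
(solving `Var(log s²) = trigamma(d/2) + trigamma(d0/2)` with a Newton
inversion of the trigamma function), giving the posterior variance
`s̃² = (d0·s0² + d·s²)/(d0 + d)` and a moderated t on `d0 + d` df. The fit
coincides with limma's moment estimator to machine precision, and limma
serves as an independent cross-check in the tests — not as the
implementation. `d0 = 0` reduces to the ordinary pooled t-test and
`d0 = ∞` to a pooled-variance z-test; both limits are verified numerically.

Multiple testing uses Benjamini–Hochberg q-values with the discovery
threshold `q ≤ 0.01`. Annotation-category and pathway overrepresentation is
a one-sided ("greater") Fisher exact test per category against the measured
gene universe; no correction is applied across categories, matching how
such per-category asterisks are conventionally reported — downstream users
should treat the category p-values as descriptive.

# Subtyping

Each tumor's log-ratio profile against the mean of the normal references is
correlated with class centroids over the genes shared between profile and
signature. G-CIMP positivity requires a strictly positive correlation
(`r = 0` is negative). The four-class assignment takes the class of maximal
correlation, requiring `max r > min_r` with `min_r = 0` by default; exact
ties and all-nonpositive correlation vectors are `unclassifiable` rather
than guessed. Missing signature genes are dropped, not imputed — the
remaining signature genes carry the centroid's direction redundantly.

# Progression-group aggregation

Decoded state calls are tallied per gene within each progression group.
The frequent-set rule is **inclusive**: a gene is frequently altered when
it carries the same directional call in *at least* 50% of the group's pairs
(a gene altered in exactly half the pairs is kept; at the 0.5 boundary a
gene can, in principle, sit in both directions' sets, and the tests assert
both boundary behaviors). Cross-group comparisons enumerate all Venn
regions per direction plus opposite-direction overlaps. Average alteration
profiles mean the log-ratios over exactly the pairs carrying the
corresponding call, so underexpression profiles are negative and
overexpression profiles positive by construction on clean data.

# Variant summaries

Variant identity is the `(chrom, pos, ref, alt)` key; duplicate keys within
a sample are an error, not silently collapsed. Pair-level gene mutation
frequencies support two scopes because "recurrently mutated" is ambiguous
in practice: `shared-in-pair` (the same key in both tumors) and
`any-sample` (either tumor carries any variant in the gene). Both are
first-class; the demo reports both. Functional tallies define `exonic` as
nonsynonymous + stop + synonymous.

# The synthetic cohort generator

The generator's defaults are the study conditions the package is exercised
under: 21 patient-matched pairs split 6/5/10 over A2→A3, A2→G4 and A3→G4,
four normal brain references, 2,000 genes evenly spread over 10
chromosomes, expression noise 0.5 log2 units. Planted structure:

* **Copy-number events**: whole-chromosome and segmental events define
  three copy-number subgroups (present in both tumors of a pair), plus a
  whole-chromosome-10 deletion planted *only in recurrent tumors* — the
  hallmark event whose calls the tests check (never in initial, always in
  recurrent samples). Segment means carry small (sd 0.05) measurement
  noise; events shift contained genes' expression additively in log2,
  damped by the attenuation factor 0.5 (dosage effects on expression are
  damped relative to the DNA ratio; attenuation 1.0 is used in the exact
  zero-noise tests).
* **Expression subgroups**: three subgroups with disjoint 150-gene marker
  panels shifted by ±2 log2 units. This is deliberately the dominant
  genome-wide structure, so the three major clusters of the cohort are the
  planted subgroups.
* **Subtype centroids**: a 200-gene panel with random normal centroids for
  proneural / neural / classical / mesenchymal, applied at scale 1.5
  (signal-to-noise 3 against the 0.5 noise), and a 50-gene G-CIMP centroid
  at scale 0.75 with G-CIMP-negative tumors loading negatively.
  Class effects are kept smaller than subgroup-marker effects because
  subtype structure in such cohorts is sub-dominant at genome scale
  (visible as subclusters, not as the major partition). Initial proneural
  tumors always recur mesenchymal; classical recurrences split.
* **Within-pair correlation**: both tumors of a patient share a gene-wise
  deviation with sd `pair_effect_sd = 0.4` log2 units, modeling the common
  developmental history beyond copy-number coupling. This is what makes a
  subset of pairs (≈ 29% at the defaults) cluster directly together while
  discordant pairs (30% of patients have their recurrence planted in a
  different subgroup) land in different major clusters.
* **HMM truth**: state means (−3, 0, 3), emission sd 0.7, self-transitions
  0.9, uniform start; paths are drawn per chromosome.
* **Variants**: per-pair shared / initial-private / recurrent-private
  counts are Poisson with means 60 / 106 / 173 (fixable per pair through
  `variant_truth`, in which case they round-trip exactly); each pair draws
  from a disjoint position range so keys never collide across pairs. Three
  driver genes are planted: two shared-at-the-same-key in ~70% and ~60% of
  pairs, one mutated in both tumors at *different* positions in ~40% —
  exercising both frequency scopes.

Determinism: every draw comes from a named substream (a 31-bit hash of the
base seed and a unit label, fed to Mersenne–Twister), so a fixed seed gives
byte-identical cohorts across runs and platforms, and generating additional
samples never perturbs earlier ones. The discordant-pair allocation is
taken from the cohort tail, which is the one deterministic design feature
that depends on the cohort size.

What the generator does **not** emulate: count-level mean–variance
relationships of real RNA-seq (expression is simulated on the log2 scale;
counts for the preprocessing stage are derived by Poisson sampling),
batch/run effects, mutational signatures, realistic gene lengths or
linkage, and methylation (G-CIMP is planted as an expression signature
only). Passing tests therefore demonstrate correctness of the machinery on
data with planted truth, not performance on real cohorts.

# Problem sizes

The test suite and acceptance script use: 100 random instances of length
≤ 6 for the exhaustive 3^T HMM oracle; 25 profiles × 2,000 genes for
parameter recovery; the default 21-pair × 2,000-gene cohort (twice) for
clustering, subtyping and end-to-end determinism; 200 replicates of a
1,000-gene null for the realized FDR; and 20 seeds for the subtype and
variant round-trip checks. These sizes were chosen so each property is
measured with comfortable Monte-Carlo margins while the whole suite stays
interactive.

# Known limitations

* The bootstrap reports plain BP support; it is not a calibrated p-value.
* Genome-wide expression subcluster support can dip below high nominal
  levels (≈ 0.85–0.93 at the defaults) because subtype centroids and the
  recurrent-only chromosome-10 coupling cut across the planted subgroups —
  a realistic property, reported but not asserted.
* The moderated test assumes equal within-group variances and no
  covariates; the original workflow's two sequencing runs (a batch
  covariate) are out of scope.
* Arm-level event calls split chromosomes at their midpoint; the synthetic
  genome has no centromeres.
* Multi-relapse patients are reduced to (initial, last recurrence) by the
  generator's design; the pairing column structure supports any explicit
  pairing.
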