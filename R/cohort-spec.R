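#' Specification of a synthetic patient-matched astrocytoma cohort
#'
#' Describes the ground truth planted by the cohort generator: cohort size,
#' genome layout, progression-group composition, copy-number events and
#' their coupling to expression, expression-subgroup and subtype-centroid
#' effects, the generative HMM for per-pair expression-state runs, and
#' per-pair somatic-variant counts.
#'
#' The defaults mirror the study conditions of a patient-matched astrocytoma
#' progression cohort: 21 tumor pairs split over the three WHO-grade
#' progression groups A2->A3 (6 pairs), A2->G4 (5) and A3->G4 (10); four
#' normal brain reference samples; a three-state expression-ratio HMM with
#' state means (-3, 0, 3) log2 units, emission sd 0.7 and self-transition
#' probability 0.9; and per-pair somatic SNV counts with means 60 shared,
#' 106 initial-private and 173 recurrent-private.
#'
#' @param n_patients number of patient-matched tumor pairs.
#' @param n_genes number of protein-coding genes on the synthetic genome.
#' @param n_chromosomes number of chromosomes genes are spread over; must
#'   not exceed `n_genes`. Chromosomes are labeled `chr1..chrN`; planted
#'   default events use `chr10` for the recurrent-only deletion, so
#'   `n_chromosomes >= 10` is required with the default `cna_truth`.
#' @param progression_groups per-patient progression-group labels
#'   (`"A2->A3"`, `"A2->G4"`, `"A3->G4"`); defaults to the 6/5/10 split
#'   scaled to `n_patients`.
#' @param hmm_truth [hmm_params()] generating per-pair expression-state runs.
#' @param cna_truth data frame of planted copy-number events with columns
#'   `chrom`, `start`, `end` (`NA` = whole chromosome), `shift` (segment
#'   log2-ratio), `subgroup` (1-3, `NA` = all subgroups) and `stage`
#'   (`"initial"`, `"recurrent"` or `"both"`).
#' @param signature_truth list of planted expression-signal sizes (log2
#'   units) and panel sizes: `effect` (shift of each subgroup's marker
#'   genes; the dominant genome-wide structure, mirroring the three major
#'   expression subclusters such cohorts show), `class_effect` (scale of
#'   the subtype-centroid shift on the signature panel; kept smaller than
#'   `effect` because subtype structure is sub-dominant at genome scale),
#'   `gcimp_effect` (scale of the G-CIMP centroid shift; G-CIMP-negative
#'   tumors load negatively on the centroid), `n_subgroup_genes` (markers
#'   per expression subgroup), `n_class_genes` (subtype signature panel
#'   size) and `n_gcimp_genes` (G-CIMP panel size). `NULL` gives effects
#'   2 / 1.5 / 0.75 log2 units and panels scaled to the genome
#'   (150/200/50 genes at `n_genes = 2000`).
#' @param variant_truth either `NULL` (per-pair counts drawn from Poisson
#'   distributions with the default means) or a data frame with columns
#'   `patient`, `shared`, `initial_private`, `recurrent_private`.
#' @param pair_effect_sd standard deviation (log2 units) of a per-patient
#'   gene-wise expression deviation shared by both tumors of a pair. This
#'   models the common developmental history of patient-matched tumors
#'   beyond copy-number coupling and is what makes a subset of pairs
#'   cluster directly together; 0 removes all within-pair correlation
#'   beyond the planted subgroup/CNA structure.
#' @param cna_attenuation multiplicative damping of the expression shift
#'   induced by a copy-number event (dosage effects on expression are damped
#'   relative to the DNA ratio; default 0.5).
#' @param noise_sd per-measurement expression noise, log2 units (> 0).
#' @param discordant_fraction fraction of pairs whose recurrent tumor is
#'   planted in a different subgroup than its initial tumor (the cohort
#'   feature that many pairs do not co-cluster).
#' @param n_normals number of normal reference samples.
#' @param seed integer base seed; all generator draws come from named
#'   substreams derived from it (Mersenne-Twister), so a fixed seed gives
#'   byte-identical cohorts and adding samples never perturbs earlier ones.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 21,
                        n_genes = 2000,
                        n_chromosomes = 10,
                        progression_groups = NULL,
                        hmm_truth = hmm_params(sigma2 = rep(0.7^2, 3)),
                        cna_truth = NULL,
                        signature_truth = NULL,
                        variant_truth = NULL,
                        pair_effect_sd = 0.4,
                        cna_attenuation = 0.5,
                        noise_sd = 0.5,
                        discordant_fraction = 0.3,
                        n_normals = 4,
                        seed = 1) {
  if (is.null(progression_groups)) {
    progression_groups <- default_group_labels(n_patients)
  }
  if (is.null(cna_truth)) cna_truth <- default_cna_truth(n_chromosomes)
  if (is.null(signature_truth)) {
    # panel sizes scale with the genome (150/200/50 of 2000 genes)
    signature_truth <- list(effect = 2, class_effect = 1.5, gcimp_effect = 0.75,
                            n_subgroup_genes = max(2L, round(0.075 * n_genes)),
                            n_class_genes = max(2L, round(0.1 * n_genes)),
                            n_gcimp_genes = max(2L, round(0.025 * n_genes)))
  }
  spec <- structure(list(
    n_patients = as.integer(n_patients),
    n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    progression_groups = progression_groups,
    hmm_truth = hmm_truth,
    cna_truth = cna_truth,
    signature_truth = signature_truth,
    variant_truth = variant_truth,
    pair_effect_sd = pair_effect_sd,
    cna_attenuation = cna_attenuation,
    noise_sd = noise_sd,
    discordant_fraction = discordant_fraction,
    n_normals = as.integer(n_normals),
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @param spec a `cohort_spec`.
#' @export
validate_cohort_spec <- function(spec) {
  if (spec$n_genes < spec$n_chromosomes) {
    stop_named("invalid spec: n_genes (%d) < n_chromosomes (%d)",
               spec$n_genes, spec$n_chromosomes)
  }
  if (spec$n_patients < 1L) stop_named("invalid spec: n_patients must be >= 1")
  if (!(spec$noise_sd > 0)) stop_named("invalid spec: noise_sd must be > 0")
  if (is.null(spec$pair_effect_sd) || spec$pair_effect_sd < 0) {
    stop_named("invalid spec: pair_effect_sd must be >= 0")
  }
  if (length(spec$progression_groups) != spec$n_patients) {
    stop_named("invalid spec: progression_groups must have one label per patient")
  }
  bad <- setdiff(unique(spec$progression_groups),
                 c("A2->A3", "A2->G4", "A3->G4"))
  if (length(bad)) {
    stop_named("invalid spec: unknown progression group label(s): %s",
               paste(bad, collapse = ", "))
  }
  validate_hmm_params(spec$hmm_truth)
  ct <- spec$cna_truth
  need <- c("chrom", "shift", "subgroup", "stage")
  if (!all(need %in% names(ct))) {
    stop_named("invalid spec: cna_truth must have columns %s",
               paste(need, collapse = ", "))
  }
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  if (!all(ct$chrom %in% chroms)) {
    stop_named("invalid spec: cna_truth uses chromosomes outside chr1..chr%d",
               spec$n_chromosomes)
  }
  if (!all(ct$stage %in% c("initial", "recurrent", "both"))) {
    stop_named("invalid spec: cna_truth$stage must be initial/recurrent/both")
  }
  st <- spec$signature_truth
  needed <- 3 * st$n_subgroup_genes + st$n_class_genes + st$n_gcimp_genes
  if (needed > spec$n_genes) {
    stop_named("invalid spec: signature panels need %d genes but n_genes = %d",
               needed, spec$n_genes)
  }
  invisible(spec)
}

default_group_labels <- function(n_patients) {
  # 6/5/10 split of pairs over A2->A3 / A2->G4 / A3->G4, rescaled to n.
  props <- c("A2->A3" = 6, "A2->G4" = 5, "A3->G4" = 10) / 21
  counts <- floor(props * n_patients)
  while (sum(counts) < n_patients) {
    i <- which.max(props * n_patients - counts)
    counts[i] <- counts[i] + 1L
  }
  rep(names(counts), counts)
}

default_cna_truth <- function(n_chromosomes) {
  stopifnot(n_chromosomes >= 10)
  ev <- function(chrom, shift, subgroup, stage, start = NA_real_, end = NA_real_) {
    data.frame(chrom = chrom, start = start, end = end, shift = shift,
               subgroup = subgroup, stage = stage, stringsAsFactors = FALSE)
  }
  rbind(
    # recurrent-only whole-chromosome-10 deletion, all subgroups
    ev("chr10", -1.0, NA, "recurrent"),
    # subgroup-defining events present in both tumors of a pair
    ev("chr1", -0.8, 1, "both"),
    ev("chr7", +0.8, 1, "both"),
    ev("chr5", +0.6, 1, "both", start = 0, end = 1e5), # sub-chromosomal segment
    ev("chr2", +0.8, 2, "both"),
    ev("chr9", -0.8, 2, "both"),
    ev("chr3", -0.8, 3, "both"),
    ev("chr4", +0.8, 3, "both")
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d pairs + %d normals, %d genes on %d chromosomes\n",
              x$n_patients, x$n_normals, x$n_genes, x$n_chromosomes))
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$progression_groups)),
                                 table(x$progression_groups)), collapse = " "), "\n")
  cat(sprintf("  noise_sd=%.2f attenuation=%.2f seed=%d\n",
              x$noise_sd, x$cna_attenuation, x$seed))
  invisible(x)
}
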