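# Synthetic patient-matched cohort generator with planted ground truth.
#
# Every stochastic draw comes from a named substream (see substream_seed),
# so a fixed spec$seed yields byte-identical cohorts and generating more
# samples never perturbs earlier ones.

#' Simulate a patient-matched astrocytoma cohort
#'
#' Generates, for each patient, an initial and a recurrent tumor sample plus
#' normal reference samples: a log2 expression matrix, SEG-style copy-number
#' segments, a sample sheet, subtype signature centroids, and the full
#' planted truth. Planted copy-number events shift the mean expression of
#' contained genes additively in log2 space, damped by
#' `spec$cna_attenuation`; expression subgroups get disjoint marker-gene
#' shifts; subtype classes get centroid-shaped shifts on a signature panel.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `astro_cohort` with elements `expr` (genes x
#'   samples log2 matrix), `segments` (data frame `sample`, `chrom`,
#'   `start`, `end`, `seg_mean`; 0-based half-open), `samples` (sample
#'   sheet), `gene_map`, `signatures` (class centroids), `gcimp_signature`,
#'   `truth`, and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  gm <- build_gene_map(spec)
  sheet <- build_sample_sheet(spec)
  tumor <- sheet[sheet$stage != "normal", ]

  baseline <- with_substream(spec$seed, "baseline",
                             rnorm(spec$n_genes, mean = 5, sd = 2))
  names(baseline) <- gm$gene

  panels <- plant_signature_panels(spec, gm)

  # patient-specific deviation shared by both tumors of a pair (common
  # developmental history beyond the planted subgroup/CNA structure)
  patients <- unique(sheet$patient[sheet$stage != "normal"])
  pair_effect <- vapply(patients, function(pid) {
    if (spec$pair_effect_sd > 0) {
      with_substream(spec$seed, paste0("paireffect:", pid),
                     rnorm(spec$n_genes, 0, spec$pair_effect_sd))
    } else {
      numeric(spec$n_genes)
    }
  }, numeric(spec$n_genes))
  colnames(pair_effect) <- patients

  expr <- matrix(0, spec$n_genes, nrow(sheet),
                 dimnames = list(gm$gene, sheet$sample_id))
  seg_list <- vector("list", nrow(tumor))
  planted_shift <- matrix(0, spec$n_genes, nrow(tumor),
                          dimnames = list(gm$gene, tumor$sample_id))

  for (i in seq_len(nrow(sheet))) {
    s <- sheet[i, ]
    mu <- baseline
    if (s$stage != "normal") {
      segs <- resolve_segments(spec, gm, s$subgroup, s$stage)
      noisy <- segs
      noisy$seg_mean <- segs$shift +
        with_substream(spec$seed, paste0("seg:", s$sample_id),
                       rnorm(nrow(segs), 0, 0.05))
      noisy$sample <- s$sample_id
      j <- match(s$sample_id, tumor$sample_id)
      seg_list[[j]] <- noisy[, c("sample", "chrom", "start", "end", "seg_mean")]

      cn_shift <- gene_shift_from_segments(gm, segs) * spec$cna_attenuation
      sg_shift <- panels$subgroup_effect[, s$subgroup]
      cls_shift <- if (!is.na(s$subtype)) panels$class_effect[, s$subtype] else 0
      # G-CIMP-negative tumors load negatively on the centroid, so their
      # signature correlation is planted negative rather than merely absent
      gc_shift <- if (isTRUE(s$gcimp)) panels$gcimp_effect else -panels$gcimp_effect
      total <- cn_shift + sg_shift + cls_shift + gc_shift + pair_effect[, s$patient]
      planted_shift[, j] <- total
      mu <- mu + total
    }
    noise <- with_substream(spec$seed, paste0("expr:", s$sample_id),
                            rnorm(spec$n_genes, 0, spec$noise_sd))
    expr[, i] <- mu + noise
  }

  truth <- list(
    subgroup = setNames(tumor$subgroup, tumor$sample_id),
    subtype = setNames(tumor$subtype, tumor$sample_id),
    gcimp = setNames(tumor$gcimp, tumor$sample_id),
    baseline = baseline,
    planted_shift = planted_shift,
    subgroup_markers = panels$subgroup_markers,
    class_panel = rownames(panels$class_centroids),
    gcimp_panel = names(panels$gcimp_centroid)
  )

  structure(list(expr = expr,
                 segments = do.call(rbind, seg_list),
                 samples = sheet,
                 gene_map = gm,
                 signatures = panels$class_centroids,
                 gcimp_signature = panels$gcimp_centroid,
                 truth = truth,
                 spec = spec),
            class = "astro_cohort")
}

build_sample_sheet <- function(spec) {
  n <- spec$n_patients
  patients <- sprintf("P%02d", seq_len(n))
  groups <- spec$progression_groups
  grade_i <- ifelse(groups == "A3->G4", "A3", "A2")
  grade_r <- ifelse(groups == "A2->A3", "A3", "G4")
  sg_i <- ((seq_len(n) - 1L) %% 3L) + 1L
  sg_r <- sg_i
  n_disc <- ceiling(spec$discordant_fraction * n)
  if (n_disc > 0) {
    disc <- seq.int(n - n_disc + 1L, n)
    sg_r[disc] <- (sg_i[disc] %% 3L) + 1L
  }
  idh1 <- ifelse(sg_i == 2L, "wt", "mut")
  classes <- c("proneural", "classical", "mesenchymal")
  cls_i <- classes[((seq_len(n) - 1L) %% 3L) + 1L]
  cls_r <- ifelse(cls_i == "proneural", "mesenchymal",
           ifelse(cls_i == "classical",
                  ifelse(seq_len(n) %% 2L == 0L, "mesenchymal", "classical"),
                  "mesenchymal"))
  treatment <- c("none", "RT", "RT+TMZ", "RT+chemo")[((seq_len(n) - 1L) %% 4L) + 1L]

  tumor <- data.frame(
    sample_id = c(paste0(patients, "-I"), paste0(patients, "-R")),
    patient = c(patients, patients),
    stage = rep(c("initial", "recurrent"), each = n),
    grade = c(grade_i, grade_r),
    group = c(groups, groups),
    subgroup = c(sg_i, sg_r),
    subtype = c(cls_i, cls_r),
    gcimp = rep(idh1 == "mut", 2L),
    idh1 = c(idh1, idh1),
    treatment = c(treatment, treatment),
    stringsAsFactors = FALSE
  )
  ord <- order(tumor$patient, tumor$stage)
  tumor <- tumor[ord, ]
  normals <- data.frame(
    sample_id = sprintf("NB%d", seq_len(spec$n_normals)),
    patient = NA_character_, stage = "normal", grade = NA_character_,
    group = NA_character_, subgroup = NA_integer_, subtype = NA_character_,
    gcimp = NA, idh1 = NA_character_, treatment = NA_character_,
    stringsAsFactors = FALSE
  )
  out <- rbind(tumor, normals)
  rownames(out) <- NULL
  out
}

plant_signature_panels <- function(spec, gm) {
  st <- spec$signature_truth
  n_needed <- 3L * st$n_subgroup_genes + st$n_class_genes + st$n_gcimp_genes
  stopifnot(n_needed <= spec$n_genes)
  picked <- with_substream(spec$seed, "panels",
                           sample.int(spec$n_genes, n_needed))
  idx <- split(picked, rep(c("sg1", "sg2", "sg3", "class", "gcimp"),
                           c(st$n_subgroup_genes, st$n_subgroup_genes,
                             st$n_subgroup_genes, st$n_class_genes,
                             st$n_gcimp_genes)))

  subgroup_effect <- matrix(0, spec$n_genes, 3, dimnames = list(gm$gene, NULL))
  markers <- list()
  for (k in 1:3) {
    g <- idx[[paste0("sg", k)]]
    sign_pattern <- rep(c(1, -1), length.out = length(g))
    subgroup_effect[g, k] <- st$effect * sign_pattern
    markers[[k]] <- gm$gene[g]
  }

  classes <- c("proneural", "neural", "classical", "mesenchymal")
  cen <- with_substream(spec$seed, "signatures",
                        matrix(rnorm(st$n_class_genes * length(classes)),
                               st$n_class_genes, length(classes),
                               dimnames = list(gm$gene[idx$class], classes)))
  class_effect <- matrix(0, spec$n_genes, length(classes),
                         dimnames = list(gm$gene, classes))
  class_effect[idx$class, ] <- (st$class_effect %||% st$effect) * cen

  gcen <- with_substream(spec$seed, "gcimp",
                         setNames(rnorm(st$n_gcimp_genes), gm$gene[idx$gcimp]))
  gcimp_effect <- setNames(numeric(spec$n_genes), gm$gene)
  gcimp_effect[idx$gcimp] <- (st$gcimp_effect %||% (st$effect / 2)) * gcen

  list(subgroup_effect = subgroup_effect, subgroup_markers = markers,
       class_centroids = cen, class_effect = class_effect,
       gcimp_centroid = gcen, gcimp_effect = gcimp_effect)
}

# Full-coverage planted segments for one sample (subgroup sg, stage st).
resolve_segments <- function(spec, gm, sg, stage) {
  lens <- attr(gm, "chrom_lengths")
  ct <- spec$cna_truth
  keep <- (is.na(ct$subgroup) | ct$subgroup == sg) &
    (ct$stage == "both" | ct$stage == stage)
  ev <- ct[keep, , drop = FALSE]
  out <- list()
  for (chrom in names(lens)) {
    L <- lens[[chrom]]
    e <- ev[ev$chrom == chrom, , drop = FALSE]
    if (nrow(e)) {
      e$start[is.na(e$start)] <- 0
      e$end[is.na(e$end)] <- L
      e$start <- pmax(0, e$start)
      e$end <- pmin(L, e$end)
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
        stop_named("overlapping planted events on %s", chrom)
      }
    }
    pos <- 0
    segs <- list()
    if (nrow(e)) {
      for (r in seq_len(nrow(e))) {
        if (e$start[r] > pos) {
          segs[[length(segs) + 1L]] <- c(pos, e$start[r], 0)
        }
        segs[[length(segs) + 1L]] <- c(e$start[r], e$end[r], e$shift[r])
        pos <- e$end[r]
      }
    }
    if (pos < L) segs[[length(segs) + 1L]] <- c(pos, L, 0)
    m <- do.call(rbind, segs)
    out[[chrom]] <- data.frame(chrom = chrom, start = m[, 1], end = m[, 2],
                               shift = m[, 3], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Planted per-gene shift implied by event segments (midpoint containment).
gene_shift_from_segments <- function(gm, segs) {
  shift <- setNames(numeric(nrow(gm)), gm$gene)
  mid <- (gm$start + gm$end) / 2
  for (chrom in unique(segs$chrom)) {
    s <- segs[segs$chrom == chrom & segs$shift != 0, , drop = FALSE]
    if (!nrow(s)) next
    on_chrom <- which(gm$chrom == chrom)
    for (r in seq_len(nrow(s))) {
      hit <- on_chrom[mid[on_chrom] >= s$start[r] & mid[on_chrom] < s$end[r]]
      shift[hit] <- shift[hit] + s$shift[r]
    }
  }
  shift
}

#' Simulate per-pair chromosomally ordered expression-state profiles
#'
#' For each patient, hidden expression states are drawn per chromosome from
#' the Markov chain in `spec$hmm_truth` (each chromosome restarts from the
#' initial distribution) and observations from the state-specific normal
#' emissions. The planted state paths are recorded as truth.
#'
#' @param spec a [cohort_spec()].
#' @param gene_map optional precomputed [build_gene_map()] result.
#' @return a list of class `pair_profiles` with `values` (genes x patients
#'   log2-ratio matrix), `states` (planted states, coded -1/0/+1),
#'   `gene_map` and `patients`.
#' @export
simulate_pair_profiles <- function(spec, gene_map = NULL) {
  validate_cohort_spec(spec)
  p <- spec$hmm_truth
  validate_hmm_params(p)
  gm <- gene_map %||% build_gene_map(spec)
  bounds <- chrom_boundaries(gm)
  patients <- sprintf("P%02d", seq_len(spec$n_patients))
  values <- matrix(NA_real_, nrow(gm), length(patients),
                   dimnames = list(gm$gene, patients))
  states <- matrix(NA_integer_, nrow(gm), length(patients),
                   dimnames = list(gm$gene, patients))
  sdv <- sqrt(p$sigma2)
  for (k in seq_along(patients)) {
    with_substream(spec$seed, paste0("pair:", patients[k]), {
      for (b in seq_len(nrow(bounds))) {
        len <- bounds$last[b] - bounds$first[b] + 1L
        s <- integer(len)
        s[1] <- sample.int(3L, 1L, prob = p$pi)
        if (len > 1) {
          for (t in 2:len) s[t] <- sample.int(3L, 1L, prob = p$A[s[t - 1L], ])
        }
        x <- rnorm(len, mean = p$mu[s], sd = sdv[s])
        rows <- bounds$first[b]:bounds$last[b]
        states[rows, k] <- s - 2L
        values[rows, k] <- x
      }
    })
  }
  structure(list(values = values, states = states, gene_map = gm,
                 patients = patients),
            class = "pair_profiles")
}

#' Simulate paired somatic variant call sets
#'
#' Per patient, generates exactly the requested numbers of shared,
#' initial-private and recurrent-private somatic SNVs with distinct
#' `(chrom, pos, ref, alt)` keys. Each pair draws positions from its own
#' disjoint coordinate range, so keys never collide across pairs. Three
#' recurrently mutated driver genes are planted on top of (and counted
#' within) the shared calls: the first two at a pair-specific shared key in
#' ~70% and ~60% of pairs, the third mutated in both tumors of ~40% of pairs
#' but at different positions (gene-level, not key-level, sharing).
#'
#' @param spec a [cohort_spec()]; `spec$variant_truth` may fix per-pair
#'   counts, otherwise counts are Poisson with means 60 (shared), 106
#'   (initial-private) and 173 (recurrent-private).
#' @param gene_map optional precomputed gene map.
#' @param drivers plant the recurrent driver genes (default: only when
#'   per-pair counts are not fixed by `spec$variant_truth`, so that
#'   explicitly requested counts round-trip exactly).
#' @return a list of class `variant_pairs`: `pairs` (per patient, a list
#'   with `patient`, `initial` and `recurrent` variant data frames) and
#'   `truth` (planted counts and driver membership per pair).
#' @export
simulate_variant_tables <- function(spec, gene_map = NULL,
                                    drivers = is.null(spec$variant_truth)) {
  validate_cohort_spec(spec)
  gm <- gene_map %||% build_gene_map(spec)
  patients <- sprintf("P%02d", seq_len(spec$n_patients))
  driver_genes <- gm$gene[1:3]
  classes <- c("nonsynonymous", "synonymous", "stop", "intronic", "other")
  class_prob <- c(0.25, 0.12, 0.03, 0.40, 0.20)

  counts <- spec$variant_truth
  if (!is.null(counts)) {
    stopifnot(all(c("patient", "shared", "initial_private",
                    "recurrent_private") %in% names(counts)))
  }

  pairs <- vector("list", length(patients))
  truth <- data.frame(patient = patients, shared = NA_integer_,
                      initial_private = NA_integer_,
                      recurrent_private = NA_integer_,
                      driver1 = FALSE, driver2 = FALSE, driver3 = FALSE,
                      stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(patients)) {
    pid <- patients[k]
    if (is.null(counts)) {
      n3 <- with_substream(spec$seed, paste0("varcounts:", pid),
                           c(rpois(1, 60), rpois(1, 106), rpois(1, 173)))
    } else {
      row <- counts[counts$patient == pid, ]
      if (!nrow(row)) stop_named("variant_truth has no row for %s", pid)
      n3 <- c(row$shared, row$initial_private, row$recurrent_private)
    }
    n_shared <- n3[1]; n_ip <- n3[2]; n_rp <- n3[3]
    has_d <- drivers & c(k %% 10 < 7, k %% 10 < 6, k %% 10 < 4)
    # key-shared drivers consume shared slots; cap at the requested count
    n_key_drivers <- min(sum(has_d[1:2]), n_shared)
    has_d[1:2] <- has_d[1:2] & (cumsum(has_d[1:2]) <= n_key_drivers)

    pairs[[k]] <- with_substream(spec$seed, paste0("variants:", pid), {
      base_pos <- k * 1e7
      n_total <- n_shared + n_ip + n_rp + 2L * has_d[3]
      pos <- base_pos + seq_len(n_total) * 11
      gene_idx <- sample.int(nrow(gm), n_total, replace = TRUE)
      ref <- sample(bases, n_total, replace = TRUE)
      alt_off <- sample.int(3L, n_total, replace = TRUE)
      alt <- bases[(match(ref, bases) - 1L + alt_off) %% 4L + 1L]
      cls <- sample(classes, n_total, replace = TRUE, prob = class_prob)
      vaf <- round(stats::rbeta(n_total, 2, 3), 4)
      all_v <- data.frame(chrom = gm$chrom[gene_idx], pos = pos, ref = ref,
                          alt = alt, gene = gm$gene[gene_idx], class = cls,
                          vaf = vaf, stringsAsFactors = FALSE)
      # overwrite leading shared slots with key-shared drivers
      d12 <- which(has_d[1:2])
      for (j in seq_along(d12)) {
        all_v$gene[j] <- driver_genes[d12[j]]
        all_v$chrom[j] <- gm$chrom[d12[j]]
        all_v$class[j] <- "nonsynonymous"
        all_v$vaf[j] <- round(stats::rbeta(1, 4, 6), 4)
      }
      sh <- all_v[seq_len(n_shared), , drop = FALSE]
      ip <- all_v[n_shared + seq_len(n_ip), , drop = FALSE]
      rp <- all_v[n_shared + n_ip + seq_len(n_rp), , drop = FALSE]
      if (has_d[3]) {
        # gene-level sharing at distinct positions: one extra call per tumor
        extra <- all_v[n_shared + n_ip + n_rp + 1:2, , drop = FALSE]
        extra$gene <- driver_genes[3]
        extra$chrom <- gm$chrom[3]
        extra$class <- "nonsynonymous"
        ip <- rbind(ip, extra[1, ])
        rp <- rbind(rp, extra[2, ])
      }
      initial <- rbind(sh, ip)
      recurrent <- rbind(sh, rp)
      initial$sample <- paste0(pid, "-I")
      recurrent$sample <- paste0(pid, "-R")
      cols <- c("sample", "chrom", "pos", "ref", "alt", "gene", "class", "vaf")
      list(patient = pid,
           initial = initial[, cols],
           recurrent = recurrent[, cols])
    })
    truth[k, c("shared", "initial_private", "recurrent_private")] <-
      c(n_shared, n_ip + has_d[3], n_rp + has_d[3])
    truth[k, c("driver1", "driver2", "driver3")] <- has_d
  }
  names(pairs) <- patients
  structure(list(pairs = pairs, truth = truth, driver_genes = driver_genes),
            class = "variant_pairs")
}
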