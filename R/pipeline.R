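# End-to-end orchestration: simulate -> preprocess -> cnv -> clustering ->
# de -> hmm -> subtype -> progression -> mutations, with plain-text
# intermediates and a checksummed manifest.

#' Default pipeline configuration
#'
#' All stage parameters with their package defaults; unknown keys in a user
#' config are rejected by [run_pipeline()].
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out = NULL,
    cohort = list(n_patients = 21L, n_genes = 2000L, n_chromosomes = 10L,
                  noise_sd = 0.5, discordant_fraction = 0.3, n_normals = 4L,
                  pair_effect_sd = 0.4, cna_attenuation = 0.5),
    cpm = list(offset = 0.5),
    normalization = list(span = 0.7, cycles = 3L),
    clustering = list(k = 3L, bootstrap = 100L),
    de = list(q = 0.01),
    hmm = list(init_means = c(-3, 0, 3), init_sigma2 = c(1, 1, 1),
               self_transition = 0.9, max_iter = 200L, tol = 1e-4,
               concat_genome = FALSE),
    subtype = list(min_r = 0),
    progression = list(min_fraction = 0.5),
    mutations = list(scope = "shared-in-pair")
  )
}

check_config_keys <- function(config, reference, path = "") {
  unknown <- setdiff(names(config), names(reference))
  if (length(unknown)) {
    stop_named("unknown config key(s): %s",
               paste0(path, unknown, collapse = ", "))
  }
  for (nm in names(config)) {
    if (is.list(reference[[nm]]) && !is.null(names(reference[[nm]]))) {
      if (is.list(config[[nm]])) {
        check_config_keys(config[[nm]], reference[[nm]], paste0(path, nm, "."))
      }
    }
  }
  invisible(TRUE)
}

merge_config <- function(user, reference) {
  for (nm in names(user)) {
    if (is.list(reference[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(reference[[nm]]))) {
      reference[[nm]] <- merge_config(user[[nm]], reference[[nm]])
    } else {
      reference[[nm]] <- user[[nm]]
    }
  }
  reference
}

#' Synthetic gene annotation categories and pathways
#'
#' Draws a reproducible annotation table over the gene universe: the
#' functional categories used in enrichment summaries (EG, OG, TS, CC, PO,
#' KI, MG, SG, TF) and ten signaling-pathway-style gene sets.
#'
#' @param gene_map a [build_gene_map()] result.
#' @param seed integer seed.
#' @return named list: category -> gene vector.
#' @export
simulate_annotations <- function(gene_map, seed = 1) {
  genes <- gene_map$gene
  cats <- c(EG = 300, OG = 120, TS = 120, CC = 150, PO = 80, KI = 100,
            MG = 200, SG = 250, TF = 220)
  sizes <- pmin(cats, length(genes))
  annot <- lapply(seq_along(sizes), function(i) {
    with_substream(seed, paste0("annot:", names(sizes)[i]),
                   sample(genes, sizes[i]))
  })
  names(annot) <- names(sizes)
  for (i in 1:10) {
    nm <- sprintf("pathway_%02d", i)
    annot[[nm]] <- with_substream(seed, paste0("annot:", nm),
                                  sample(genes, 40))
  }
  annot
}

#' Run the full demo pipeline on a simulated cohort
#'
#' Simulates a patient-matched cohort, then runs every stage in order
#' (preprocess, copy number, clustering, differential expression, HMM
#' state calling, subtyping, progression aggregation, mutation summaries),
#' writing plain-text artifacts (TSV/JSON/GMT/VCF) plus a manifest with an
#' MD5 checksum per file. With a fixed seed the manifest is byte-identical
#' across runs.
#'
#' @param config configuration list (see [default_config()]); partial
#'   configs are merged over the defaults, unknown keys rejected. May also
#'   be a path to a YAML file.
#' @param out output directory (overrides `config$out`); required.
#' @param seed overrides `config$seed`.
#' @return invisibly, a list with the main in-memory results and
#'   `manifest` (data frame `file`, `md5`).
#' @export
run_pipeline <- function(config = list(), out = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ref <- default_config()
  check_config_keys(config, ref)
  cfg <- merge_config(config, ref)
  if (!is.null(out)) cfg$out <- out
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$out)) stop_named("config error: output directory 'out' is not set")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(cfg$out, "vcf"), showWarnings = FALSE)
  p <- function(...) file.path(cfg$out, ...)

  ## --- simulate -------------------------------------------------------
  spec <- cohort_spec(n_patients = cfg$cohort$n_patients,
                      n_genes = cfg$cohort$n_genes,
                      n_chromosomes = cfg$cohort$n_chromosomes,
                      noise_sd = cfg$cohort$noise_sd,
                      discordant_fraction = cfg$cohort$discordant_fraction,
                      n_normals = cfg$cohort$n_normals,
                      pair_effect_sd = cfg$cohort$pair_effect_sd,
                      cna_attenuation = cfg$cohort$cna_attenuation,
                      seed = cfg$seed)
  cohort <- simulate_cohort(spec)
  gm <- cohort$gene_map
  sheet <- cohort$samples
  write_tsv(cohort$expr, p("expression_log2.tsv"), id_col = "gene")
  write_seg(cohort$segments, p("segments.seg"))
  write_tsv(sheet, p("samples.tsv"))
  write_tsv(gm, p("gene_map.tsv"))
  write_signature_gmt(cohort$signatures, p("subtype_signatures.gmt"))
  write_signature_gmt(list(GCIMP = cohort$gcimp_signature), p("gcimp_signature.gmt"))
  write_tsv(data.frame(sample = names(cohort$truth$subgroup),
                       subgroup = cohort$truth$subgroup,
                       subtype = cohort$truth$subtype,
                       gcimp = cohort$truth$gcimp),
            p("truth_samples.tsv"))

  tumors <- sheet$sample_id[sheet$stage != "normal"]
  normals <- sheet$sample_id[sheet$stage == "normal"]
  pairs <- data.frame(
    patient = unique(sheet$patient[sheet$stage != "normal"]),
    stringsAsFactors = FALSE)
  pairs$initial <- paste0(pairs$patient, "-I")
  pairs$recurrent <- paste0(pairs$patient, "-R")

  ## --- preprocess -----------------------------------------------------
  counts <- matrix(
    with_substream(cfg$seed, "counts",
                   rpois(length(cohort$expr), lambda = pmax(2^cohort$expr, 1e-8))),
    nrow = nrow(cohort$expr), dimnames = dimnames(cohort$expr))
  counts_f <- filter_low_expression(counts)
  lcpm <- log_cpm(counts_f, offset = cfg$cpm$offset)
  norm <- cyclic_loess_normalize(lcpm, span = cfg$normalization$span,
                                 n_cycles = cfg$normalization$cycles)
  gm_f <- gm[gm$gene %in% rownames(norm), ]
  attr(gm_f, "chrom_lengths") <- attr(gm, "chrom_lengths")
  write_tsv(norm, p("expression_normalized.tsv"), id_col = "gene")

  ## --- copy number ----------------------------------------------------
  cn_prof <- segments_to_genes(cohort$segments, gm)
  write_tsv(cn_prof, p("cnv_gene_profiles.tsv"), id_col = "gene")
  cn_tree <- ward_tree(corr_distance(t(cn_prof)))
  cn_cl <- cut_major_clusters(cn_tree, cfg$clustering$k)
  avg_prof <- vapply(sort(unique(cn_cl)), function(k) {
    average_profile(cn_prof[, names(cn_cl)[cn_cl == k], drop = FALSE])
  }, numeric(nrow(cn_prof)))
  colnames(avg_prof) <- paste0("cluster", sort(unique(cn_cl)))
  write_tsv(avg_prof, p("cnv_cluster_average_profiles.tsv"), id_col = "gene")
  events <- call_chromosome_events(cn_prof, gm)
  write_tsv(events, p("cnv_chromosome_events.tsv"))
  write_dendrogram_newick(cn_tree, p("cnv_dendrogram.nwk"))
  cn_adj <- matched_pair_adjacency(cn_tree, pairs, k = cfg$clustering$k)
  write_tsv(cn_adj, p("cnv_pair_adjacency.tsv"))
  cn_boot <- bootstrap_support(t(cn_prof), cn_tree,
                               B = cfg$clustering$bootstrap, seed = cfg$seed)
  write_tsv(data.frame(node = seq_along(cn_boot), support = cn_boot),
            p("cnv_bootstrap_support.tsv"))

  ## --- expression clustering ------------------------------------------
  X <- t(norm[, tumors, drop = FALSE])
  ex_tree <- ward_tree(corr_distance(X))
  write_dendrogram_newick(ex_tree, p("expression_dendrogram.nwk"))
  ex_cl <- cut_major_clusters(ex_tree, cfg$clustering$k)
  ex_adj <- matched_pair_adjacency(ex_tree, pairs, k = cfg$clustering$k)
  write_tsv(data.frame(sample = names(ex_cl), cluster = ex_cl),
            p("expression_clusters.tsv"))
  write_tsv(ex_adj, p("expression_pair_adjacency.tsv"))

  ## --- differential expression ----------------------------------------
  annot <- simulate_annotations(gm, seed = cfg$seed)
  write_gmt(annot, p("annotations.gmt"))
  de_results <- lapply(sort(unique(ex_cl)), function(k) {
    moderated_two_group_test(norm, names(ex_cl)[ex_cl == k], normals,
                             q_cut = cfg$de$q)
  })
  names(de_results) <- paste0("cluster", sort(unique(ex_cl)))
  for (nm in names(de_results)) {
    write_tsv(de_results[[nm]], p(sprintf("de_%s.tsv", nm)))
  }
  vd <- de_sets_and_venn(de_results, threshold = cfg$de$q)
  jsonlite::write_json(vd$venn, p("de_venn.json"), auto_unbox = TRUE, digits = NA)
  enr <- do.call(rbind, lapply(names(de_results), function(nm) {
    sets <- vd$sets[[nm]]
    do.call(rbind, lapply(c("under", "over"), function(dir) {
      e <- category_enrichment(sets[[dir]], rownames(norm), annot)
      e$cluster <- nm; e$direction <- dir
      e
    }))
  }))
  write_tsv(enr, p("de_enrichment.tsv"))

  ## --- HMM state calling ----------------------------------------------
  profiles <- simulate_pair_profiles(spec, gene_map = gm)
  write_tsv(profiles$values, p("pair_logratio_profiles.tsv"), id_col = "gene")
  st <- cfg$hmm$self_transition
  A0 <- matrix((1 - st) / 2, 3, 3); diag(A0) <- st
  init <- hmm_params(mu = cfg$hmm$init_means, sigma2 = cfg$hmm$init_sigma2,
                     A = A0)
  fit <- fit_hmm(profiles, init = init, max_iter = cfg$hmm$max_iter,
                 tol = cfg$hmm$tol, concat_genome = cfg$hmm$concat_genome)
  jsonlite::write_json(
    list(pi = fit$params$pi, A = fit$params$A, mu = fit$params$mu,
         sigma2 = fit$params$sigma2, loglik = fit$loglik_trace,
         n_iter = fit$n_iter, converged = fit$converged),
    p("hmm_params.json"), digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  decoding <- posterior_decode(profiles, fit$params)
  dec_df <- data.frame(
    gene = rep(rownames(decoding$labels), ncol(decoding$labels)),
    patient = rep(colnames(decoding$labels), each = nrow(decoding$labels)),
    p_under = as.vector(decoding$posterior[, 1, ]),
    p_unchanged = as.vector(decoding$posterior[, 2, ]),
    p_over = as.vector(decoding$posterior[, 3, ]),
    label = as.vector(decoding$labels))
  write_tsv(dec_df, p("hmm_decoding.tsv"))

  ## --- subtype ---------------------------------------------------------
  logratios <- tumor_logratio_vs_normal(norm, normals)
  calls <- subtype_cohort(logratios, cohort$signatures,
                          gcimp_sig = cohort$gcimp_signature,
                          min_r = cfg$subtype$min_r)
  write_tsv(calls, p("subtype_calls.tsv"))
  trans <- transition_table(calls, pairs)
  write_tsv(as.data.frame.table(trans, responseName = "n"),
            p("subtype_transitions.tsv"))

  ## --- progression -----------------------------------------------------
  groups <- progression_groups(sheet)
  counts_sum <- group_alteration_counts(decoding, groups)
  freq <- frequent_sets(counts_sum, min_fraction = cfg$progression$min_fraction)
  jsonlite::write_json(freq$venn, p("progression_venn.json"),
                       auto_unbox = TRUE, digits = NA)
  for (g in names(freq$sets)) {
    for (dir in c("under", "over")) {
      fn <- p(sprintf("frequent_%s_%s.txt", gsub("[^A-Za-z0-9]", "", g), dir))
      writeLines(freq$sets[[g]][[dir]], fn)
      prof <- average_alteration_profile(profiles, decoding, groups[[g]],
                                         direction = dir,
                                         genes = freq$sets[[g]][[dir]])
      write_tsv(prof, p(sprintf("alteration_profile_%s_%s.tsv",
                                gsub("[^A-Za-z0-9]", "", g), dir)))
    }
  }
  pw <- pathway_alteration_profile(freq, annot, rownames(decoding$labels))
  write_tsv(pw, p("progression_pathways.tsv"))

  ## --- mutations -------------------------------------------------------
  vars <- simulate_variant_tables(spec, gene_map = gm)
  for (pp in vars$pairs) {
    write_vcf(pp$initial, p("vcf", paste0(pp$patient, "-I.vcf")))
    write_vcf(pp$recurrent, p("vcf", paste0(pp$patient, "-R.vcf")))
  }
  sp <- t(vapply(vars$pairs, function(pp) {
    shared_private(pp$initial, pp$recurrent)
  }, numeric(3)))
  write_tsv(data.frame(patient = rownames(sp), sp), p("mutation_shared_private.tsv"))
  tallies <- do.call(rbind, lapply(vars$pairs, function(pp) {
    rbind(data.frame(sample = pp$initial$sample[1] %||% NA,
                     t(functional_tally(pp$initial))),
          data.frame(sample = pp$recurrent$sample[1] %||% NA,
                     t(functional_tally(pp$recurrent))))
  }))
  write_tsv(tallies, p("mutation_functional_tally.tsv"))
  gf <- gene_frequency(vars, scope = cfg$mutations$scope)
  write_tsv(head(gf, 50), p("mutation_gene_frequency.tsv"))
  gf_groups <- gene_frequency(vars, scope = cfg$mutations$scope, groups = groups)
  write_tsv(do.call(rbind, lapply(split(gf_groups, gf_groups$group), head, 20)),
            p("mutation_gene_frequency_by_group.tsv"))

  ## --- manifest --------------------------------------------------------
  cfg_echo <- cfg
  cfg_echo$out <- NULL  # keep the echo (and manifest) path-independent
  yaml::write_yaml(cfg_echo, p("config.yaml"))
  files <- sort(setdiff(list.files(cfg$out, recursive = TRUE), "manifest.json"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(cfg$out, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(config = cfg, spec = spec, cohort = cohort,
                 normalized = norm, cn_profiles = cn_prof,
                 cn_clusters = cn_cl, expression_clusters = ex_cl,
                 de = de_results, hmm_fit = fit, decoding = decoding,
                 subtype_calls = calls, transitions = trans,
                 frequent = freq, variants = vars, manifest = manifest))
}
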