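## cli_pipeline: orchestrates simulate -> map -> tails -> quantify ->
## catalog -> targets -> enrichment, with a one-call demo and a written
## report bundle. All randomness flows from the config seeds.

#' File-based pipeline configuration
#'
#' @param genome path to a genome FASTA.
#' @param loci path to a loci GFF3.
#' @param reads named character vector of collapsed-FASTA paths (names are
#'   library ids; the first is the quantification stage).
#' @param spikes path to a spike-in TSV (`spike_id`, `seq`, `fmol`).
#' @param utrs path to a merged-UTR FASTA.
#' @param de named character vector of DE TSV paths (names are comparison
#'   labels).
#' @param n_eggs eggs pooled per library for absolute quantification.
#' @param reference_fmol optional known amount (fmol/library) of the
#'   endogenous reference microRNA `reference_mature` (e.g. a qPCR
#'   estimate); both must be given to add an endogenous-reference estimate.
#' @param reference_mature mature id of the endogenous reference.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, loci, reads, spikes, utrs, de,
                            n_eggs = 1, reference_fmol = NULL,
                            reference_mature = NULL) {
  cfg <- list(genome = genome, loci = loci, reads = reads, spikes = spikes,
              utrs = utrs, de = de, n_eggs = n_eggs,
              reference_fmol = reference_fmol,
              reference_mature = reference_mature)
  for (field in c("genome", "loci", "spikes", "utrs")) {
    if (is.null(cfg[[field]]) || !file.exists(cfg[[field]])) {
      abort(paste0("pipeline_config: missing or nonexistent input for field '",
                   field, "'"))
    }
  }
  for (field in c("reads", "de")) {
    paths <- cfg[[field]]
    if (length(paths) == 0 || is.null(names(paths)) || !all(file.exists(paths))) {
      abort(paste0("pipeline_config: missing or nonexistent input for field '",
                   field, "'"))
    }
  }
  structure(cfg, class = "pipeline_config")
}

## load a pipeline_config into the in-memory shape run_pipeline uses
load_pipeline_inputs <- function(cfg) {
  genome <- read_genome_fasta(cfg$genome)
  list(
    genome = genome,
    loci = read_loci_gff3(cfg$loci, genome = genome),
    libraries = purrr::map(cfg$reads, read_collapsed_fasta),
    spikes = read_spikes_tsv(cfg$spikes),
    utrs = read_utr_fasta(cfg$utrs),
    de_tables = purrr::map(cfg$de, read_de_tsv),
    n_eggs = cfg$n_eggs,
    reference_fmol = cfg$reference_fmol,
    reference_mature = cfg$reference_mature,
    truth = NULL,
    rng_seed = 1L
  )
}

## mir_sim -> the same in-memory shape (truth available for recovery report)
sim_pipeline_inputs <- function(sim) {
  list(genome = sim$genome, loci = sim$loci, libraries = sim$libraries,
       spikes = sim$spikes, utrs = sim$utrs, de_tables = sim$de_tables,
       n_eggs = sim$config$n_eggs,
       reference_fmol = sim$truth$reference_fmol,
       reference_mature = sim$truth$reference_mature,
       truth = sim$truth, rng_seed = sim$config$rng_seed)
}

#' Run the full analysis pipeline
#'
#' Maps and counts every library, normalizes to RPM, calls 3' tails,
#' estimates absolute microRNA content of the quantification library from
#' the spike-ins (at one and two allowed mismatches) and optionally from an
#' endogenous reference, computes all-versus-all stage correlations,
#' clusters loci and groups seed families, predicts canonical targets,
#' runs the enrichment battery and flags candidate clearance microRNAs.
#' When the input is a simulation (or [sim_config()]) a recovery-vs-truth
#' table is appended.
#'
#' @param x a [sim_config()], a `mir_sim`, or a [pipeline_config()].
#' @param out_dir optional directory for the report bundle (TSV/JSON).
#' @param max_mismatches mismatch allowance for expression counting.
#' @param min_class weakest site class counted as targeting.
#' @param max_gap locus clustering distance (bases).
#' @param seed_k seed length for family grouping.
#' @param n_perm permutations per enrichment test.
#' @param p_threshold Bonferroni-corrected cutoff for clearance flagging.
#' @param fold_threshold,alpha DE classification thresholds.
#' @param tail_stages library ids to run tail calling on (default: all).
#' @return list of class `mir_pipeline` with elements `counts`, `rpm`,
#'   `mapping_summary`, `tails` (named list of `tail_summary`), `absolute`,
#'   `correlation`, `clusters`, `families`, `sites`, `pairs`, `enrichment`,
#'   `words`, `clearance`, `recovery` (NULL without truth) and `params`.
#' @export
run_pipeline <- function(x = sim_config(), out_dir = NULL,
                         max_mismatches = 1, min_class = "7mer-A1",
                         max_gap = 10000, seed_k = 6, n_perm = 1000,
                         p_threshold = 0.001, fold_threshold = 2,
                         alpha = 0.05, tail_stages = NULL) {
  inputs <- if (inherits(x, "sim_config")) {
    sim_pipeline_inputs(simulate_dataset(x))
  } else if (inherits(x, "mir_sim")) {
    sim_pipeline_inputs(x)
  } else if (inherits(x, "pipeline_config")) {
    load_pipeline_inputs(x)
  } else {
    abort("x must be a sim_config, mir_sim or pipeline_config")
  }

  genome <- inputs$genome
  loci <- inputs$loci
  libs <- inputs$libraries
  quant_stage <- names(libs)[1]

  ## mapping + counting + RPM
  counts <- count_matrix(libs, genome, loci, max_mismatches = max_mismatches)
  rpm_mat <- rpm(counts)
  mapping_summary <- attr(counts, "summary")

  ## 3' tail calling (always includes the quantification stage, whose
  ## tail-recovered reads feed the absolute estimates)
  tail_stages <- union(quant_stage, tail_stages %||% names(libs))
  tails <- purrr::map(setNames(tail_stages, tail_stages), function(stage) {
    summarize_tails(call_tails(libs[[stage]], genome, loci = loci))
  })

  ## absolute quantification from spike-ins (1 and 2 mismatches) and the
  ## endogenous reference
  spikes <- inputs$spikes
  spike_counts <- vapply(spikes$seq, function(s) {
    i <- match(as_dna(s), as_dna(libs[[quant_stage]]$seq))
    if (is.na(i)) 0 else libs[[quant_stage]]$count[i]
  }, numeric(1))
  absolute <- list()
  for (mm in unique(c(max_mismatches, 2))) {
    cnts <- if (mm == max_mismatches) counts else {
      count_matrix(libs[quant_stage], genome, loci, max_mismatches = mm)
    }
    total_reads <- sum(cnts[[quant_stage]])
    est <- absolute_quantify(total_reads, spike_counts, spikes$fmol,
                             n_eggs = inputs$n_eggs,
                             reference = paste0("spike-in:", spikes$spike_id))
    est$mismatches <- mm
    if (!is.null(inputs$reference_fmol) && !is.null(inputs$reference_mature)) {
      ref_reads <- cnts[[quant_stage]][match(inputs$reference_mature,
                                             cnts$mature_id)]
      ## total excludes nothing: the reference is itself a microRNA
      est_endo <- absolute_quantify(total_reads, ref_reads,
                                    inputs$reference_fmol,
                                    n_eggs = inputs$n_eggs,
                                    reference = "endogenous")
      est_endo$mismatches <- mm
      est <- dplyr::bind_rows(est, est_endo)
    }
    absolute[[paste0("mm", mm)]] <- est
  }
  ## tail-inclusive totals: reads recovered by the 3'-trimming caller are
  ## genuine microRNA reads that full-length mapping misses, so the least
  ## biased totals include them (for the endogenous reference numerator
  ## and denominator lose the same fraction either way)
  pm <- tails[[quant_stage]]$per_mature
  tot_ti <- sum(pm$total)
  est_ti <- absolute_quantify(tot_ti, spike_counts, spikes$fmol,
                              n_eggs = inputs$n_eggs,
                              reference = paste0("spike-in:", spikes$spike_id))
  est_ti$mismatches <- NA_real_
  if (!is.null(inputs$reference_fmol) && !is.null(inputs$reference_mature)) {
    ref_ti <- pm$total[match(inputs$reference_mature, pm$mature_id)]
    endo_ti <- absolute_quantify(tot_ti, ref_ti, inputs$reference_fmol,
                                 n_eggs = inputs$n_eggs,
                                 reference = "endogenous")
    endo_ti$mismatches <- NA_real_
    est_ti <- dplyr::bind_rows(est_ti, endo_ti)
  }
  est_ti$totals <- "tail_inclusive"
  absolute <- dplyr::bind_rows(absolute)
  absolute$totals <- "full_length_mapping"
  absolute <- dplyr::bind_rows(absolute, est_ti)

  correlation <- stage_correlation(rpm_mat)

  ## catalog
  clusters <- cluster_loci(loci, max_gap = max_gap)
  matures <- loci %>% dplyr::select("mature_id", "mature_seq")
  families <- seed_families(matures, k = seed_k)

  ## targets
  utrs <- inputs$utrs
  sites <- find_sites(matures, utrs)
  pairs <- predict_targets(matures, utrs, min_class = min_class, sites = sites)

  ## enrichment
  classified <- purrr::map(inputs$de_tables, classify_genes,
                           fold_threshold = fold_threshold, alpha = alpha)
  universe <- intersect(utrs$gene, unique(unlist(purrr::map(classified, "gene"))))
  enrichment <- enrich_mirnas(pairs, classified, universe, matures = matures,
                              n_perm = n_perm,
                              rng_seed = inputs$rng_seed + 7L)
  early <- names(classified)[1]
  down_early <- intersect(classified[[early]]$gene[
    classified[[early]]$class == "down"], universe)
  words <- word_enrich(utrs, down_early, universe, k = 6)
  expr <- tibble(mature_id = rpm_mat$mature_id,
                 expression = rpm_mat[[early]] %||% rpm_mat[[quant_stage]])
  clearance <- rank_mirnas(enrichment, expr, p_threshold = p_threshold)

  ## recovery vs truth
  recovery <- NULL
  if (!is.null(inputs$truth)) {
    truth <- inputs$truth
    flagged <- sort(clearance$mature_id[clearance$flagged])
    seed_words <- revcomp(as_dna(truth$family_seeds))
    recovery <- tibble(
      check = c("clearance_flagged_equals_planted",
                "predicted_pairs_equal_truth",
                "planted_seed_word_in_top10"),
      pass = c(
        identical(flagged, truth$clearance_matures),
        identical(
          sort(paste(pairs$mature_id, pairs$gene)),
          sort(paste(truth$pairs$mature_id, truth$pairs$gene))),
        any(words$rank[match(seed_words, words$word)] <= 10, na.rm = TRUE)
      )
    )
  }

  result <- structure(list(
    counts = counts, rpm = rpm_mat, mapping_summary = mapping_summary,
    tails = tails, absolute = absolute, correlation = correlation,
    clusters = clusters, families = families, sites = sites, pairs = pairs,
    enrichment = enrichment, words = words, clearance = clearance,
    recovery = recovery,
    params = list(max_mismatches = max_mismatches, min_class = min_class,
                  max_gap = max_gap, seed_k = seed_k, n_perm = n_perm,
                  p_threshold = p_threshold, fold_threshold = fold_threshold,
                  alpha = alpha, quant_stage = quant_stage,
                  early_comparison = early,
                  bonferroni_family = attr(enrichment, "bonferroni_family"))
  ), class = "mir_pipeline")

  if (!is.null(out_dir)) write_pipeline_bundle(result, out_dir)
  result
}

#' Run the default end-to-end demo
#'
#' Simulates the default dataset, runs the full pipeline and returns the
#' result (writing the report bundle when `out_dir` is given).
#'
#' @param out_dir optional output directory.
#' @param rng_seed seed for the simulation.
#' @param ... passed to [run_pipeline()].
#' @export
run_demo <- function(out_dir = NULL, rng_seed = 20260924, ...) {
  run_pipeline(sim_config(rng_seed = rng_seed), out_dir = out_dir, ...)
}

#' Write the pipeline report bundle to a directory
#' @param result a `mir_pipeline`.
#' @param dir output directory.
#' @export
write_pipeline_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(as_tibble(result$counts), file.path(dir, "counts.tsv"))
  readr::write_tsv(as_tibble(result$rpm), file.path(dir, "rpm.tsv"))
  readr::write_tsv(result$mapping_summary, file.path(dir, "mapping_summary.tsv"))
  readr::write_tsv(result$absolute, file.path(dir, "absolute_estimates.tsv"))
  readr::write_tsv(tidy(result$correlation), file.path(dir, "stage_correlation.tsv"))
  write_cluster_bed(result$clusters, file.path(dir, "clusters.bed"))
  readr::write_tsv(
    dplyr::mutate(result$families,
                  members = purrr::map_chr(.data$members, paste, collapse = ",")),
    file.path(dir, "seed_families.tsv"))
  readr::write_tsv(result$sites, file.path(dir, "target_sites.tsv"))
  readr::write_tsv(result$pairs, file.path(dir, "target_pairs.tsv"))
  readr::write_tsv(result$enrichment, file.path(dir, "enrichment.tsv"))
  readr::write_tsv(result$words, file.path(dir, "word_enrichment.tsv"))
  readr::write_tsv(result$clearance, file.path(dir, "clearance_mirnas.tsv"))
  for (stage in names(result$tails)) {
    readr::write_tsv(result$tails[[stage]]$per_mature,
                     file.path(dir, paste0("tails_", stage, ".tsv")))
  }
  report <- list(
    params = result$params,
    tail_overall = purrr::map(result$tails, ~ as.list(.x$overall)),
    absolute = result$absolute,
    flagged_clearance = result$clearance$mature_id[result$clearance$flagged],
    recovery = result$recovery
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write locus clusters as BED (cluster span, members in the name field)
#' @param clusters tibble from [cluster_loci()].
#' @param path file path.
#' @export
write_cluster_bed <- function(clusters, path) {
  bed <- clusters %>%
    dplyr::group_by(.data$cluster_id, .data$chrom) %>%
    dplyr::summarise(start = min(.data$hairpin_start),
                     end = max(.data$hairpin_end),
                     name = paste0(.data$cluster_id[1], "|",
                                   paste(.data$locus_id, collapse = ",")),
                     .groups = "drop") %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::select("chrom", "start", "end", "name")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @export
print.mir_pipeline <- function(x, ...) {
  cat("<mir_pipeline>\n")
  cat(sprintf("  libraries: %s\n",
              paste(setdiff(names(x$counts), "mature_id"), collapse = ", ")))
  cat(sprintf("  flagged clearance microRNAs: %s\n",
              paste(x$clearance$mature_id[x$clearance$flagged], collapse = ", ")))
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery vs truth: %d/%d checks pass\n",
                sum(x$recovery$pass), nrow(x$recovery)))
  }
  invisible(x)
}
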