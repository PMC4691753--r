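## synthetic_data: a fully specified toy dataset (genome, microRNA loci,
## stage libraries, spike-ins, UTRs, DE tables) with a machine-readable
## truth record, so every downstream stage is testable without downloads.
##
## The generator emulates a developmental small-RNA study: reads are the
## templated mature sequence plus an optional nontemplated 3' tail drawn
## from a length/composition model dominated by short adenosine runs;
## spike-ins of known molar amount are mixed into each library at a depth
## coherent with a stated total microRNA content per egg; 3' UTRs carry
## planted canonical sites for a small set of "clearance" microRNAs that
## switch on after zygotic genome activation and target the maternally
## down-regulated gene class.

#' Nontemplated 3'-tail model
#'
#' @param prob per-read modification probability in `[0, 1]`.
#' @param length_probs probabilities of tail lengths 1..5 (must sum to 1).
#' @param base_probs 5x4 matrix of per-position nucleotide probabilities
#'   (columns A, C, G, T; rows positions 1..5, each summing to 1). The
#'   default is strongly adenosine-dominated, as observed for microRNA
#'   3'-end additions in animal small-RNA libraries.
#' @return list of class `tail_model`.
#' @export
tail_model <- function(prob = 0.2,
                       length_probs = c(0.55, 0.30, 0.10, 0.04, 0.01),
                       base_probs = NULL) {
  if (is.null(base_probs)) {
    base_probs <- rbind(
      c(0.95, 0.02, 0.01, 0.02),
      matrix(rep(c(0.85, 0.05, 0.05, 0.05), 4), nrow = 4, byrow = TRUE)
    )
    colnames(base_probs) <- c("A", "C", "G", "T")
  }
  stopifnot(prob >= 0, prob <= 1, length(length_probs) == 5,
            abs(sum(length_probs) - 1) < 1e-8,
            nrow(base_probs) == 5, ncol(base_probs) == 4,
            all(abs(rowSums(base_probs) - 1) < 1e-8))
  structure(list(prob = prob, length_probs = length_probs,
                 base_probs = base_probs), class = "tail_model")
}

#' Simulate nontemplated 3' tailing of a mature microRNA
#'
#' With probability `model$prob` a tail of length 1..5 (drawn from
#' `model$length_probs`) is appended, each tail base drawn from the
#' per-position probabilities; otherwise the mature sequence is returned
#' unchanged. The output alphabet follows the input (RNA in, RNA out).
#'
#' @param mature_seq mature sequence (nonempty).
#' @param model a [tail_model()].
#' @param n number of reads to draw.
#' @param rng_seed optional seed for a deterministic draw.
#' @return character vector of `n` read sequences.
#' @export
simulate_tail <- function(mature_seq, model = tail_model(), n = 1,
                          rng_seed = NULL) {
  stopifnot(nchar(mature_seq) > 0)
  mature_seq <- toupper(mature_seq)
  is_rna <- grepl("U", mature_seq, fixed = TRUE)
  draw <- function() {
    tails <- draw_tails(model, n)
    if (is_rna) tails <- as_rna(tails)
    paste0(mature_seq, tails)
  }
  if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
}

## vector of n tails (possibly ""), DNA alphabet
draw_tails <- function(model, n) {
  if (n == 0L) return(character(0))
  modified <- stats::runif(n) < model$prob
  tails <- character(n)
  if (any(modified)) {
    lens <- sample.int(5L, sum(modified), replace = TRUE,
                       prob = model$length_probs)
    tails[modified] <- vapply(lens, function(len) {
      paste(vapply(seq_len(len), function(p) {
        sample(colnames(model$base_probs), 1L,
               prob = model$base_probs[p, ])
      }, character(1)), collapse = "")
    }, character(1))
  }
  tails
}

#' Plant a canonical target site into a UTR by substitution
#'
#' Overwrites the UTR at each 0-based offset with the class-defining site
#' string of the given mature microRNA; output length equals input length.
#' Planted intervals are tracked in attribute `planted`, and planting over
#' a previously planted interval is an error.
#'
#' @param utr UTR sequence (DNA).
#' @param mature_seq mature microRNA sequence (>= 9 nt).
#' @param site_class one of `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"`.
#' @param positions integer vector of 0-based offsets of the site 5' ends.
#' @return the modified UTR string with an updated `planted` attribute
#'   (tibble `start`, `end`, 0-based half-open).
#' @export
plant_sites <- function(utr, mature_seq, site_class, positions) {
  if (!site_class %in% SITE_CLASSES) abort("unknown site class")
  if (length(positions) == 0L) return(utr)
  site <- site_patterns(mature_seq)[[site_class]]
  w <- nchar(site)
  n <- nchar(utr)
  if (any(positions < 0 | positions + w > n)) {
    abort("site does not fit in the UTR at the requested position")
  }
  new_iv <- tibble(start = as.integer(positions),
                   end = as.integer(positions) + w)
  old_iv <- attr(utr, "planted") %||% tibble(start = integer(), end = integer())
  all_iv <- dplyr::bind_rows(old_iv, new_iv) %>% dplyr::arrange(.data$start)
  if (nrow(all_iv) > 1 &&
      any(all_iv$start[-1] < all_iv$end[-nrow(all_iv)])) {
    abort("planted site collides with a previously planted site")
  }
  out <- utr
  for (p in positions) substr(out, p + 1, p + w) <- site
  attr(out, "planted") <- all_iv
  out
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults define the study conditions the package's tests run under:
#' a 2 x 100-kb genome carrying 12 microRNA hairpins (one 3-locus cluster,
#' one 2-locus cluster, 7 singletons), five developmental libraries
#' (oocyte, 0-5 h, 8-16 h, 16-24 h, 24-48 h), four clearance microRNAs
#' from the seed families AGUACG (x2), AGUACA and CACUGG that switch on at
#' 8-16 h and target the maternally down-regulated gene class, two
#' spike-ins, 0.2 fmol of total microRNA per egg with 10 eggs per library,
#' and a 20% tailing probability with adenosine-dominated composition.
#'
#' @param rng_seed integer seed; all randomness flows from it.
#' @param n_chromosomes,chrom_length genome shape.
#' @param cluster_plan tibble (`chrom`, `start`, `n_members`, `spacing`)
#'   describing hairpin placement; consecutive members start `spacing`
#'   bases apart. Singletons are rows with `n_members = 1`.
#' @param hairpin_len,mature_len hairpin and mature-arm lengths (bases).
#' @param stages library names, first one is the quantification stage.
#' @param expression optional tibble (`locus`, one column per stage) of
#'   expected read counts for the dominant 3p arm; a default plan is built
#'   when `NULL`.
#' @param minor_arm_ratio 5p-arm expected reads as a fraction of 3p.
#' @param clearance_loci indices of loci acting as clearance microRNAs.
#' @param reference_locus index of the endogenous-reference locus.
#' @param seed_plan named character vector, `mature_id` -> RNA positions
#'   2..8, forcing seed identity (family structure) of designed 3p arms.
#' @param tail_prob per-microRNA modification probability (scalar or one
#'   value per locus).
#' @param tail_model_spec a [tail_model()] (its `prob` is overridden per
#'   locus by `tail_prob`).
#' @param end_variation_prob probability of +/-1-nt templated 3'-end
#'   variation, default 0.
#' @param spike_plan tibble (`spike_id`, `fmol`) of spike-ins per library.
#' @param total_fmol_per_egg,n_eggs absolute microRNA content per egg and
#'   eggs pooled per library; fixes the read depth per fmol.
#' @param n_genes,utr_length gene universe for targeting.
#' @param n_down,n_up sizes of the always-down and always-up gene classes.
#' @param targets_per_clearance down-class genes targeted per clearance
#'   microRNA; `offtargets_per_clearance` additional none-class targets.
#' @param comparisons stage-versus-oocyte DE comparisons emitted.
#' @param fold_threshold,alpha thresholds the planted DE classes obey.
#' @param scrub_chance_sites remove chance seed-match sites from UTRs so
#'   planted targeting is exactly the truth.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 20260924,
                       n_chromosomes = 2,
                       chrom_length = 100000,
                       cluster_plan = NULL,
                       hairpin_len = 70,
                       mature_len = 22,
                       stages = c("oocyte", "e0_5h", "e8_16h", "e16_24h", "e24_48h"),
                       expression = NULL,
                       minor_arm_ratio = 0.05,
                       clearance_loci = c(1, 2, 3, 6),
                       reference_locus = 8,
                       seed_plan = NULL,
                       tail_prob = 0.2,
                       tail_model_spec = tail_model(),
                       end_variation_prob = 0,
                       spike_plan = tibble(spike_id = c("spike1", "spike2"),
                                           fmol = c(1, 2)),
                       total_fmol_per_egg = 0.2,
                       n_eggs = 10,
                       n_genes = 250,
                       utr_length = 400,
                       n_down = 40,
                       n_up = 40,
                       targets_per_clearance = 25,
                       offtargets_per_clearance = 3,
                       comparisons = c("e8_16h", "e16_24h", "e24_48h"),
                       fold_threshold = 2,
                       alpha = 0.05,
                       scrub_chance_sites = TRUE) {
  if (is.null(cluster_plan)) {
    cluster_plan <- tibble(
      chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2", "chr2"),
      start = c(5000, 30000, 60000, 75000, 90000, 5000, 20000, 35000, 50000),
      n_members = c(3, 2, 1, 1, 1, 1, 1, 1, 1),
      spacing = c(3000, 9200, 0, 0, 0, 0, 0, 0, 0)
    )
  }
  n_loci <- sum(cluster_plan$n_members)
  locus_ids <- sprintf("tca-mir-%02d", seq_len(n_loci))
  if (is.null(seed_plan)) {
    m3p <- function(i) sprintf("%s-3p", sub("mir", "miR", locus_ids[i]))
    seed_plan <- setNames(
      c("AGUACGU", "AGUACGU", "AGUACAU", "CACUGGU"),
      vapply(clearance_loci, m3p, character(1))
    )
  }
  if (length(tail_prob) == 1) tail_prob <- rep(tail_prob, n_loci)
  stopifnot(length(tail_prob) == n_loci, all(tail_prob >= 0 & tail_prob <= 1),
            all(comparisons %in% stages), n_down + n_up < n_genes,
            targets_per_clearance <= n_down)
  if (is.null(expression)) {
    base <- 150 + 20 * (seq_len(n_loci) %% 6)
    expr <- matrix(rep(base, length(stages)), nrow = n_loci,
                   dimnames = list(locus_ids, stages))
    expr[clearance_loci, c("oocyte", "e0_5h")[c("oocyte", "e0_5h") %in% stages]] <- 5
    late <- setdiff(stages, c("oocyte", "e0_5h"))
    expr[clearance_loci, late] <- rep(c(400, 350, 300), length.out = length(late) *
                                        length(clearance_loci))
    expr[reference_locus, ] <- 600
    expression <- expr
  }
  structure(list(
    rng_seed = rng_seed, n_chromosomes = n_chromosomes,
    chrom_length = chrom_length, cluster_plan = cluster_plan,
    hairpin_len = hairpin_len, mature_len = mature_len, stages = stages,
    expression = expression, minor_arm_ratio = minor_arm_ratio,
    clearance_loci = clearance_loci, reference_locus = reference_locus,
    seed_plan = seed_plan, tail_prob = tail_prob,
    tail_model_spec = tail_model_spec,
    end_variation_prob = end_variation_prob, spike_plan = spike_plan,
    total_fmol_per_egg = total_fmol_per_egg, n_eggs = n_eggs,
    n_genes = n_genes, utr_length = utr_length, n_down = n_down,
    n_up = n_up, targets_per_clearance = targets_per_clearance,
    offtargets_per_clearance = offtargets_per_clearance,
    comparisons = comparisons, fold_threshold = fold_threshold,
    alpha = alpha, scrub_chance_sites = scrub_chance_sites,
    locus_ids = locus_ids, n_loci = n_loci
  ), class = "sim_config")
}

## ---- internals ------------------------------------------------------------

## lay out hairpins from the cluster plan; error on overlap / out of bounds
build_locus_coords <- function(config) {
  rows <- list()
  idx <- 0L
  for (r in seq_len(nrow(config$cluster_plan))) {
    cp <- config$cluster_plan[r, ]
    for (m in seq_len(cp$n_members)) {
      idx <- idx + 1L
      start <- cp$start + (m - 1L) * cp$spacing
      rows[[idx]] <- tibble(locus_id = config$locus_ids[idx],
                            chrom = cp$chrom, strand = "+",
                            hairpin_start = start,
                            hairpin_end = start + config$hairpin_len)
    }
  }
  loci <- dplyr::bind_rows(rows)
  if (any(loci$hairpin_end > config$chrom_length) ||
      !all(loci$chrom %in% paste0("chr", seq_len(config$n_chromosomes)))) {
    abort("cluster plan places a hairpin outside its chromosome")
  }
  ov <- loci %>% dplyr::arrange(.data$chrom, .data$hairpin_start) %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(clash = .data$hairpin_start < dplyr::lag(.data$hairpin_end,
                                                           default = -1L)) %>%
    dplyr::ungroup()
  if (any(ov$clash)) {
    bad <- ov$locus_id[ov$clash][1]
    abort(paste0("planted loci overlap (", bad, "); adjust the cluster plan"))
  }
  loci
}

## per-arm annotation + genome carrying designed 3p seeds
build_loci <- function(config, genome) {
  coords <- build_locus_coords(config)
  ml <- config$mature_len
  arms <- list()
  for (i in seq_len(nrow(coords))) {
    lc <- coords[i, ]
    id3 <- sprintf("%s-3p", sub("mir", "miR", lc$locus_id))
    id5 <- sprintf("%s-5p", sub("mir", "miR", lc$locus_id))
    s3 <- lc$hairpin_end - ml
    seed <- config$seed_plan[id3]
    if (!is.na(seed)) {
      ## overwrite positions 2..8 of the 3p arm with the family seed
      sub <- substr(genome[[lc$chrom]], s3 + 1, lc$hairpin_end)
      substr(sub, 2, 8) <- as_dna(seed)
      substr(genome[[lc$chrom]], s3 + 1, lc$hairpin_end) <- sub
    }
    arms[[length(arms) + 1L]] <- tibble(
      locus_id = lc$locus_id,
      mature_id = c(id5, id3), arm = c("5p", "3p"),
      chrom = lc$chrom, strand = "+",
      hairpin_start = lc$hairpin_start, hairpin_end = lc$hairpin_end,
      mature_start = c(lc$hairpin_start, s3),
      mature_end = c(lc$hairpin_start + ml, lc$hairpin_end)
    )
  }
  arms <- dplyr::bind_rows(arms)
  arms$mature_seq <- as_rna(vapply(seq_len(nrow(arms)), function(i) {
    substr(genome[[arms$chrom[i]]], arms$mature_start[i] + 1, arms$mature_end[i])
  }, character(1)))
  list(loci = arms, genome = genome)
}

## simulate one library (collapsed reads + per-read truth)
simulate_library <- function(config, loci, genome, stage) {
  arms3 <- loci[loci$arm == "3p", ]
  arms5 <- loci[loci$arm == "5p", ]
  rows <- list()
  for (i in seq_len(nrow(arms3))) {
    locus_idx <- match(arms3$locus_id[i], config$locus_ids)
    w3 <- config$expression[locus_idx, stage]
    p_mod <- config$tail_prob[locus_idx]
    model <- config$tail_model_spec
    model$prob <- p_mod
    for (arm in c("3p", "5p")) {
      a <- if (arm == "3p") arms3[i, ] else arms5[i, ]
      w <- if (arm == "3p") w3 else w3 * config$minor_arm_ratio
      n <- rpois(1, w)
      if (n == 0L) next
      mature_dna <- as_dna(a$mature_seq)
      ## optional templated 3'-end variation (default off)
      ends <- rep(a$mature_end, n)
      if (config$end_variation_prob > 0) {
        shift <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                        prob = c(config$end_variation_prob / 2,
                                 1 - config$end_variation_prob,
                                 config$end_variation_prob / 2))
        ends <- ends + shift
      }
      chromseq <- genome[[a$chrom]]
      templated <- substring(chromseq, a$mature_start + 1, ends)
      tails <- draw_tails(model, n)
      seqs <- paste0(templated, tails)
      ## genomic continuation after each templated end
      cont <- substring(chromseq, ends + 1, ends + 6)
      rows[[length(rows) + 1L]] <- tibble(
        seq = seqs, mature_id = a$mature_id, planted_tail = tails,
        templated_end = ends, continuation = cont
      )
    }
  }
  reads <- dplyr::bind_rows(rows)
  if (nrow(reads) == 0L) {
    return(list(library = tibble(seq = character(), count = numeric()),
                truth = tibble()))
  }
  ## expected behaviour of the maximal-prefix trimmer
  lcp <- function(tail, cont) {
    j <- 0L
    while (j < nchar(tail) &&
           substr(tail, j + 1, j + 1) == substr(cont, j + 1, j + 1)) {
      j <- j + 1L
    }
    j
  }
  truth <- reads %>%
    dplyr::count(.data$seq, .data$mature_id, .data$planted_tail,
                 .data$continuation, .data$templated_end, name = "count") %>%
    dplyr::mutate(
      templated_prefix = as.integer(purrr::map2_int(
        .data$planted_tail, .data$continuation, lcp)),
      expected_tail = substr(.data$planted_tail,
                             .data$templated_prefix + 1,
                             nchar(.data$planted_tail)),
      detectable = nchar(.data$planted_tail) > 0 &
        .data$templated_prefix < nchar(.data$planted_tail),
      first_base_detectable = nchar(.data$planted_tail) > 0 &
        substr(.data$planted_tail, 1, 1) != substr(.data$continuation, 1, 1)
    )
  library <- truth %>%
    dplyr::group_by(.data$seq) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  list(library = library, truth = truth)
}

## spike-ins: sequences absent from the genome, counts at the coherent depth
simulate_spikes <- function(config, genome, lib_depths) {
  gss <- genome_stringset(genome)
  seqs <- character(nrow(config$spike_plan))
  for (i in seq_along(seqs)) {
    repeat {
      cand <- random_dna(1, config$mature_len)
      hits <- map_read(gss, cand, max_mismatches = 0)
      if (nrow(hits) == 0L) break
    }
    seqs[i] <- cand
  }
  sp <- config$spike_plan
  sp$seq <- seqs
  counts <- purrr::imap(lib_depths, function(d, stage) {
    rpois(nrow(sp), d * sp$fmol)
  })
  for (stage in names(counts)) sp[[paste0("count_", stage)]] <- counts[[stage]]
  sp
}

## plant targeting into UTRs, scrub chance sites, return utrs + truth.
## Truth sites/pairs are derived by an independent brute-force substring
## scan of the final UTRs, so the truth record reflects exactly what was
## emitted even if a rare seed-word collision survives placement.
build_targeting <- function(config, loci, utr_seqs, gene_ids, gene_class) {
  matures <- loci %>% dplyr::select("mature_id", "mature_seq")
  pats <- purrr::map(setNames(matures$mature_seq, matures$mature_id),
                     site_patterns)
  cores <- unique(vapply(pats, function(p) p$core, character(1)))

  clearance_ids <- names(config$seed_plan)
  down_genes <- gene_ids[gene_class == "down"]
  none_genes <- gene_ids[gene_class == "none"]
  ## background miRNA with unenriched targets (first non-clearance 3p arm)
  all3p <- loci$mature_id[loci$arm == "3p"]
  background_id <- setdiff(all3p, clearance_ids)[1]

  plan <- list()
  for (mid in clearance_ids) {
    tg <- sample(down_genes, config$targets_per_clearance)
    og <- sample(none_genes, config$offtargets_per_clearance)
    plan[[length(plan) + 1L]] <- tibble(
      mature_id = mid, gene = c(tg, og),
      class = sample(c("8mer", "7mer-m8", "7mer-A1"), length(c(tg, og)),
                     replace = TRUE, prob = c(0.4, 0.3, 0.3)))
  }
  plan[[length(plan) + 1L]] <- tibble(
    mature_id = background_id, gene = sample(gene_ids, 12),
    class = sample(c("8mer", "7mer-m8", "7mer-A1"), 12, replace = TRUE))
  plan <- dplyr::bind_rows(plan) %>%
    dplyr::distinct(.data$mature_id, .data$gene, .keep_all = TRUE)

  planted <- purrr::map(setNames(utr_seqs, gene_ids), function(u) {
    tibble(start = integer(), end = integer())
  })
  has_foreign_core <- function(window, own_core) {
    any(vapply(setdiff(cores, own_core), function(cr) {
      grepl(cr, window, fixed = TRUE)
    }, logical(1)))
  }
  realized_class <- function(utr, pos, w, has_m8_pattern) {
    ## class of the own core after substitution, from the flanks
    core_start <- if (has_m8_pattern) pos + 1L else pos
    before <- if (core_start > 0) substr(utr, core_start, core_start) else ""
    after <- if (core_start + 7 <= nchar(utr)) {
      substr(utr, core_start + 7, core_start + 7)
    } else ""
    list(before = before, after = after)
  }
  utrs <- setNames(utr_seqs, gene_ids)
  for (r in seq_len(nrow(plan))) {
    mid <- plan$mature_id[r]
    g <- plan$gene[r]
    cls <- plan$class[r]
    site <- pats[[mid]][[cls]]
    w <- nchar(site)
    best_cand <- NULL; best_pos <- NA_integer_
    for (try in 1:200) {
      pos <- sample.int(config$utr_length - w + 1L, 1L) - 1L
      iv <- planted[[g]]
      if (nrow(iv) > 0 && any(pos < iv$end + 7 & pos + w > iv$start - 7)) next
      cand <- utrs[[g]]
      substr(cand, pos + 1, pos + w) <- site
      if (is.null(best_cand)) { best_cand <- cand; best_pos <- pos }
      ## the realized class must be exactly the requested one
      has_m8 <- cls %in% c("7mer-m8", "8mer")
      fl <- realized_class(cand, pos, w, has_m8)
      up_m8 <- !has_m8 && fl$before == pats[[mid]]$m8_comp
      up_a1 <- cls %in% c("6mer", "7mer-m8") && fl$after == "A"
      if (up_m8 || up_a1) next
      window <- substr(cand, max(1, pos - 5), min(nchar(cand), pos + w + 5))
      if (has_foreign_core(window, pats[[mid]]$core)) next
      best_cand <- cand; best_pos <- pos
      break
    }
    utrs[[g]] <- best_cand
    planted[[g]] <- dplyr::bind_rows(
      planted[[g]], tibble(start = best_pos, end = best_pos + w))
  }

  if (config$scrub_chance_sites) {
    utrs <- scrub_sites(utrs, cores, planted)
  }

  utr_tbl <- tibble(gene = gene_ids, utr_seq = unname(utrs[gene_ids]),
                    n_transcripts = 1L)
  sites <- truth_scan_sites(utr_tbl, matures)
  pairs <- sites %>%
    dplyr::filter(site_class_rank(.data$class) >= site_class_rank("7mer-A1")) %>%
    dplyr::distinct(.data$mature_id, .data$gene) %>%
    dplyr::arrange(.data$mature_id, .data$gene)

  list(utrs = utr_tbl, plan = dplyr::arrange(plan, .data$mature_id, .data$gene),
       sites = sites, pairs = pairs, background_mature = background_id)
}

## brute-force site enumeration over sliding windows; independent of
## find_sites (no shared scanning code beyond the pattern definitions)
truth_scan_sites <- function(utrs, matures) {
  rows <- list()
  for (mi in seq_len(nrow(matures))) {
    p <- site_patterns(matures$mature_seq[mi])
    for (gi in seq_len(nrow(utrs))) {
      u <- utrs$utr_seq[gi]
      n <- nchar(u)
      if (n < 6) next
      win <- substring(u, 1:(n - 5), 6:n)
      core_pos <- which(win == p$core) # 1-based core starts
      if (length(core_pos) == 0L) next
      before <- ifelse(core_pos > 1, substring(u, core_pos - 1, core_pos - 1), "")
      after <- ifelse(core_pos + 6 <= n, substring(u, core_pos + 6, core_pos + 6), "")
      has_m8 <- before == p$m8_comp
      has_a1 <- after == "A"
      cls <- ifelse(has_m8 & has_a1, "8mer",
                    ifelse(has_m8, "7mer-m8",
                           ifelse(has_a1, "7mer-A1", "6mer")))
      rows[[length(rows) + 1L]] <- tibble(
        gene = utrs$gene[gi], mature_id = matures$mature_id[mi],
        class = cls, offset = as.integer(ifelse(has_m8, core_pos - 2L,
                                                core_pos - 1L)))
    }
  }
  if (length(rows) == 0L) {
    return(tibble(gene = character(), mature_id = character(),
                  class = character(), offset = integer()))
  }
  dplyr::bind_rows(rows) %>%
    dplyr::arrange(.data$mature_id, .data$gene, .data$offset)
}

## mutate a base of every unplanted seed core until none remain; cores that
## cannot be touched without damaging a planted site are left in place (the
## truth scan accounts for them)
scrub_sites <- function(utrs, cores, planted) {
  bases <- c("A", "C", "G", "T")
  for (g in names(utrs)) {
    iv <- planted[[g]]
    for (iter in 1:20) {
      u <- utrs[[g]]
      hits <- list()
      for (cr in cores) {
        loc <- stringi::stri_locate_all_fixed(u, cr, overlap = TRUE)[[1]]
        if (!is.na(loc[1, 1])) {
          hits[[length(hits) + 1L]] <- tibble(start = loc[, 1] - 1L,
                                              end = loc[, 1] + 5L)
        }
      }
      if (length(hits) == 0L) break
      hits <- dplyr::bind_rows(hits)
      ## a core is sanctioned if it lies inside a planted interval
      ok <- vapply(seq_len(nrow(hits)), function(i) {
        nrow(iv) > 0 && any(hits$start[i] >= iv$start & hits$end[i] <= iv$end)
      }, logical(1))
      bad <- hits[!ok, , drop = FALSE]
      if (nrow(bad) == 0L) break
      changed <- FALSE
      for (i in seq_len(nrow(bad))) {
        cand_pos <- seq(bad$start[i], bad$end[i] - 1L)
        outside <- cand_pos[!vapply(cand_pos, function(p) {
          nrow(iv) > 0 && any(p >= iv$start & p < iv$end)
        }, logical(1))]
        if (length(outside) == 0L) next
        p <- outside[(length(outside) + 1L) %/% 2L]
        cur <- substr(u, p + 1, p + 1)
        substr(u, p + 1, p + 1) <- sample(setdiff(bases, cur), 1L)
        changed <- TRUE
      }
      utrs[[g]] <- u
      if (!changed) break
    }
  }
  utrs
}

## planted DE tables per comparison
build_de_tables <- function(config, gene_ids, gene_class, class_by_comparison) {
  lfc_thr <- log2(config$fold_threshold)
  purrr::map(class_by_comparison, function(cls) {
    lfc <- numeric(length(gene_ids))
    padj <- numeric(length(gene_ids))
    dn <- cls == "down"; up <- cls == "up"; no <- cls == "none"
    lfc[dn] <- -stats::runif(sum(dn), lfc_thr + 0.2, 4)
    lfc[up] <- stats::runif(sum(up), lfc_thr + 0.2, 4)
    lfc[no] <- stats::runif(sum(no), -lfc_thr + 0.2, lfc_thr - 0.2)
    padj[dn | up] <- 10^stats::runif(sum(dn | up), -8, log10(config$alpha) - 0.3)
    padj[no] <- stats::runif(sum(no), config$alpha * 2, 0.95)
    tibble(gene = gene_ids, log2fc = lfc, padj = padj)
  })
}

#' Generate the full synthetic dataset with its truth record
#'
#' Deterministic given `config$rng_seed`. See [sim_config()] for what the
#' dataset emulates.
#'
#' @param config a [sim_config()].
#' @return list of class `mir_sim` with elements `genome` (named character
#'   vector), `loci` (per-arm tibble), `libraries` (named list of collapsed
#'   read tibbles `seq`, `count`, spike reads included), `spikes` (tibble
#'   with per-library observed counts), `utrs`, `de_tables` (named list per
#'   comparison), `truth` (planted quantities: per-read tails and
#'   detectability, per-microRNA detectable rates, target pairs, gene
#'   classes, spike amounts, absolute content, clearance set) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  withr::with_seed(config$rng_seed, {
    genome <- setNames(random_dna(config$n_chromosomes, config$chrom_length),
                       paste0("chr", seq_len(config$n_chromosomes)))
    built <- build_loci(config, genome)
    genome <- built$genome
    loci <- built$loci

    ## matures must be unique words in the genome
    gss <- genome_stringset(genome)
    for (i in seq_len(nrow(loci))) {
      hits <- map_read(gss, as_dna(loci$mature_seq[i]), max_mismatches = 0)
      if (nrow(hits) != 1L) {
        abort(paste0("mature arm ", loci$mature_id[i],
                     " is not a unique genomic word; use another rng_seed"))
      }
    }

    libs <- list(); read_truth <- list()
    for (stage in config$stages) {
      sim <- simulate_library(config, loci, genome, stage)
      libs[[stage]] <- sim$library
      read_truth[[stage]] <- sim$truth
    }

    ## coherent sequencing depth: reads per fmol, per library
    total_fmol <- config$total_fmol_per_egg * config$n_eggs
    lib_depths <- vapply(config$stages, function(stage) {
      expected <- sum(config$expression[, stage]) * (1 + config$minor_arm_ratio)
      expected / total_fmol
    }, numeric(1))
    spikes <- simulate_spikes(config, genome, as.list(lib_depths))
    for (stage in config$stages) {
      libs[[stage]] <- dplyr::bind_rows(
        libs[[stage]],
        tibble(seq = spikes$seq, count = spikes[[paste0("count_", stage)]])
      ) %>% dplyr::filter(.data$count > 0)
    }

    ## gene universe, classes, targeting, DE
    gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
    gene_class <- rep("none", config$n_genes)
    gene_class[seq_len(config$n_down)] <- "down"
    gene_class[config$n_down + seq_len(config$n_up)] <- "up"
    gene_class <- sample(gene_class) # shuffle ids across classes
    names(gene_class) <- gene_ids
    class_by_comparison <- setNames(
      rep(list(gene_class), length(config$comparisons)), config$comparisons)
    utr_seqs <- random_dna(config$n_genes, config$utr_length)
    targ <- build_targeting(config, loci, utr_seqs, gene_ids, gene_class)
    de_tables <- build_de_tables(config, gene_ids, gene_class,
                                 class_by_comparison)

    ## per-microRNA detectable modification rates (count-weighted)
    det_rates <- purrr::imap(read_truth, function(tt, stage) {
      if (nrow(tt) == 0L) return(tibble())
      tt %>% dplyr::group_by(.data$mature_id) %>%
        dplyr::summarise(
          total = sum(.data$count),
          planted_modified = sum(.data$count[nchar(.data$planted_tail) > 0]),
          detectable_modified = sum(.data$count[.data$detectable]),
          detectable_rate = detectable_modified / total,
          .groups = "drop") %>%
        dplyr::mutate(library = stage)
    }) %>% dplyr::bind_rows()

    ref_id <- sprintf("%s-3p", sub("mir", "miR",
                                   config$locus_ids[config$reference_locus]))
    quant_stage <- config$stages[1]
    w <- config$expression[, quant_stage]
    ## equimolar-per-read bookkeeping: the reference arm's share of expected
    ## reads times the total content
    ref_fmol <- total_fmol * w[config$reference_locus] /
      (sum(w) * (1 + config$minor_arm_ratio))

    truth <- list(
      reads = read_truth,
      detectable_rates = det_rates,
      plan = targ$plan,
      sites = targ$sites,
      pairs = targ$pairs,
      gene_class = tibble(gene = gene_ids, class = unname(gene_class)),
      class_by_comparison = class_by_comparison,
      spikes = spikes,
      total_fmol_per_egg = config$total_fmol_per_egg,
      n_eggs = config$n_eggs,
      reference_mature = ref_id,
      reference_fmol = unname(ref_fmol),
      clearance_matures = sort(names(config$seed_plan)),
      background_mature = targ$background_mature,
      family_seeds = unique(substr(as_rna(config$seed_plan), 1, 6))
    )

    structure(list(genome = genome, loci = loci, libraries = libs,
                   spikes = spikes, utrs = targ$utrs, de_tables = de_tables,
                   truth = truth, config = config),
              class = "mir_sim")
  })
}

#' @export
print.mir_sim <- function(x, ...) {
  cat("<mir_sim>\n")
  cat(sprintf("  genome: %d chromosome(s), %s bases\n", length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ",")))
  cat(sprintf("  loci: %d hairpins (%d mature arms)\n",
              length(unique(x$loci$locus_id)), nrow(x$loci)))
  cat(sprintf("  libraries: %s\n", paste(names(x$libraries), collapse = ", ")))
  cat(sprintf("  genes: %d; planted target pairs: %d; clearance microRNAs: %d\n",
              nrow(x$utrs), nrow(x$truth$pairs),
              length(x$truth$clearance_matures)))
  invisible(x)
}
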