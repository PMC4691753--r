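## enrichment_stats: gene classification from differential-expression
## tables, per-microRNA target enrichment by hypergeometric and permutation
## tests with multiple-testing correction, and a set-based k-mer word
## enrichment ("sylamer-like") over 3' UTRs.

#' Classify genes from a differential-expression table
#'
#' `down` if log2 fold change <= -log2(fold_threshold) and adjusted
#' p < alpha; `up` symmetric; everything else (including genes failing
#' either threshold) is `none`. Genes with missing adjusted p are excluded
#' and counted in attribute `n_missing_padj`.
#'
#' @param de_table tibble with `gene`, `log2fc`, `padj`.
#' @param fold_threshold fold-change cutoff (linear scale), default 2.
#' @param alpha adjusted-p cutoff, default 0.05.
#' @return the table with a `class` column (`down`/`up`/`none`).
#' @export
classify_genes <- function(de_table, fold_threshold = 2, alpha = 0.05) {
  n_missing <- sum(is.na(de_table$padj))
  out <- de_table %>%
    dplyr::filter(!is.na(.data$padj)) %>%
    dplyr::mutate(class = dplyr::case_when(
      .data$log2fc <= -log2(fold_threshold) & .data$padj < alpha ~ "down",
      .data$log2fc >= log2(fold_threshold) & .data$padj < alpha ~ "up",
      TRUE ~ "none"
    ))
  attr(out, "n_missing_padj") <- n_missing
  out
}

#' Intersection gene sets across several classified comparisons
#'
#' @param classified named list of tibbles from [classify_genes()] (one per
#'   stage comparison).
#' @return list with `down` and `up`: genes carrying that class in every
#'   comparison.
#' @export
class_intersection <- function(classified) {
  stopifnot(length(classified) >= 1)
  pick <- function(cl) {
    sets <- purrr::map(classified, ~ .x$gene[.x$class == cl])
    Reduce(intersect, sets)
  }
  list(down = pick("down"), up = pick("up"))
}

#' Hypergeometric target-set enrichment
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' microRNA's targets and a gene set, drawing `n = |gene_set|` genes from a
#' universe of `N` containing `K` targets. Targets are intersected with the
#' universe first.
#'
#' @param target_genes character vector of target gene ids.
#' @param gene_set character vector, a subset of `universe`.
#' @param universe character vector of all testable genes.
#' @return one-row tibble: `N`, `K`, `n`, `k`, `p_hyper`.
#' @export
enrich_hyper <- function(target_genes, gene_set, universe) {
  if (length(universe) == 0) abort("empty gene universe")
  universe <- unique(universe)
  gene_set <- intersect(unique(gene_set), universe)
  targets <- intersect(unique(target_genes), universe)
  N <- length(universe)
  K <- length(targets)
  n <- length(gene_set)
  k <- length(intersect(targets, gene_set))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(N = N, K = K, n = n, k = k, p_hyper = p)
}

#' Permutation test of target-set enrichment
#'
#' Draws `n_perm` random gene sets of the same size from the universe
#' without replacement and compares their target overlap with the observed
#' one; the empirical p-value uses the standard +1 pseudocount,
#' `p = (1 + #\{perm >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams enrich_hyper
#' @param n_perm number of permutations, default 1000.
#' @param rng_seed optional seed making the draw deterministic.
#' @param set_size size of the permuted sets; defaults to the gene set's
#'   size within the universe and must not exceed the universe.
#' @return one-row tibble: `k` (observed), `set_size`, `n_perm`, `p_perm`.
#' @export
enrich_perm <- function(target_genes, gene_set, universe, n_perm = 1000,
                        rng_seed = NULL, set_size = NULL) {
  universe <- unique(universe)
  gene_set <- intersect(unique(gene_set), universe)
  set_size <- set_size %||% length(gene_set)
  if (set_size > length(universe)) abort("gene set larger than universe")
  targets <- intersect(unique(target_genes), universe)
  observed <- length(intersect(targets, gene_set))
  is_target <- universe %in% targets
  draw <- function() {
    sum(is_target[sample.int(length(universe), set_size)])
  }
  perm <- if (is.null(rng_seed)) {
    replicate(n_perm, draw())
  } else {
    withr::with_seed(rng_seed, replicate(n_perm, draw()))
  }
  p <- (1 + sum(perm >= observed)) / (n_perm + 1)
  tibble(k = observed, set_size = set_size, n_perm = n_perm, p_perm = p)
}

#' Multiple-testing adjustment of p-values
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param method `"bonferroni"` or `"benjamini_hochberg"`.
#' @param m family size for Bonferroni; defaults to `length(pvals)`, but a
#'   larger explicit family (e.g. microRNAs x gene sets) may be supplied.
#' @return adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "benjamini_hochberg"),
                           m = length(pvals)) {
  method <- match.arg(method)
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1]")
  }
  switch(method,
         bonferroni = pmin(1, pvals * m),
         benjamini_hochberg = p.adjust(pvals, method = "BH"))
}

#' Per-microRNA target enrichment across classified gene sets
#'
#' Runs the hypergeometric and permutation tests for every mature microRNA
#' against every supplied gene set (down/up/none per stage comparison plus
#' the all-comparison intersections) and applies a Bonferroni correction
#' whose family size is the number of microRNAs times the number of gene
#' sets.
#'
#' @param pairs target-pair table from [predict_targets()].
#' @param classified named list of classified DE tables
#'   ([classify_genes()]), one per stage comparison.
#' @param universe gene universe (genes with a UTR record and present in
#'   the DE tables).
#' @param matures optional tibble with `mature_id` forcing the microRNA
#'   set (microRNAs without predicted targets then appear with K = 0).
#' @param n_perm permutations per test, default 1000.
#' @param rng_seed seed for the permutation draws.
#' @param include_intersection also test the genes down (resp. up) in every
#'   comparison, labelled `"inters"`.
#' @return tibble with one row per microRNA x gene set: `mature_id`,
#'   `set_label`, `N`, `K`, `n`, `k`, `p_hyper`, `p_perm`, `p_bonferroni`.
#'   Attribute `bonferroni_family` records the family size used.
#' @export
enrich_mirnas <- function(pairs, classified, universe, matures = NULL,
                          n_perm = 1000, rng_seed = NULL,
                          include_intersection = TRUE) {
  universe <- unique(universe)
  mirna_ids <- sort(unique(c(pairs$mature_id, matures$mature_id)))
  sets <- list()
  for (nm in names(classified)) {
    cl <- classified[[nm]]
    for (lab in c("down", "up", "none")) {
      sets[[paste0(lab, ":", nm)]] <- intersect(cl$gene[cl$class == lab], universe)
    }
  }
  if (include_intersection && length(classified) > 1) {
    inter <- class_intersection(classified)
    sets[["down:inters"]] <- intersect(inter$down, universe)
    sets[["up:inters"]] <- intersect(inter$up, universe)
  }
  family <- length(mirna_ids) * length(sets)
  targets_by_mirna <- split(pairs$gene, pairs$mature_id)
  rows <- purrr::imap(sets, function(gene_set, lab) {
    purrr::map(mirna_ids, function(mid) {
      tg <- targets_by_mirna[[mid]] %||% character(0)
      hy <- enrich_hyper(tg, gene_set, universe)
      seed_i <- if (is.null(rng_seed)) NULL else {
        rng_seed + match(mid, mirna_ids) * 131L + match(lab, names(sets))
      }
      pm <- enrich_perm(tg, gene_set, universe, n_perm = n_perm,
                        rng_seed = seed_i)
      dplyr::bind_cols(tibble(mature_id = mid, set_label = lab),
                       hy, pm[, c("p_perm")])
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  rows$p_bonferroni <- adjust_pvalues(rows$p_hyper, "bonferroni", m = family)
  attr(rows, "bonferroni_family") <- family
  rows
}

#' Set-based k-mer word enrichment in 3' UTRs
#'
#' For each of the 4^k nucleotide words, tests whether genes whose UTR
#' contains the word are over-represented in `gene_set` relative to the
#' universe (hypergeometric upper tail, Bonferroni over all 4^k words).
#' A set-based simplification of ranked word-landscape methods; outputs are
#' labelled accordingly.
#'
#' @param utrs merged UTR tibble (`gene`, `utr_seq`) covering the universe.
#' @param gene_set character vector of genes of interest.
#' @param universe gene universe; UTRs must be available for all of it.
#' @param k word length, between 4 and 8 (default 6).
#' @return tibble with one row per word: `word` (DNA), `n_set_with_word`,
#'   `n_universe_with_word`, `p_hyper`, `p_bonferroni`, `rank` (1 = most
#'   enriched), sorted by p then word.
#' @export
word_enrich <- function(utrs, gene_set, universe, k = 6) {
  if (!(k %in% 4:8)) abort("word length k must be between 4 and 8")
  universe <- unique(universe)
  missing <- setdiff(universe, utrs$gene)
  if (length(missing)) {
    abort(paste0("no UTR record for universe gene(s): ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  gene_set <- intersect(unique(gene_set), universe)
  utr <- utrs[match(universe, utrs$gene), ]
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  pd <- Biostrings::PDict(words)
  cnt <- Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(utr$utr_seq))
  has_word <- cnt > 0  # words x genes
  in_set <- universe %in% gene_set
  N <- length(universe)
  n <- sum(in_set)
  K <- rowSums(has_word)
  kk <- rowSums(has_word[, in_set, drop = FALSE])
  p <- phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
  out <- tibble(word = words,
                n_set_with_word = as.integer(kk),
                n_universe_with_word = as.integer(K),
                p_hyper = p,
                p_bonferroni = pmin(1, p * length(words))) %>%
    dplyr::arrange(.data$p_hyper, .data$word) %>%
    dplyr::mutate(rank = dplyr::row_number())
  out
}

#' Flag candidate maternal-clearance microRNAs
#'
#' A microRNA is flagged when its targets are enriched in at least one
#' down-regulated gene set (Bonferroni-corrected p below `p_threshold`)
#' and in no up-regulated set. Expression at the stage of interest is
#' attached for expression-versus-enrichment plots.
#'
#' @param enrichment tibble from [enrich_mirnas()].
#' @param expression optional tibble with `mature_id` and `expression`
#'   (e.g. RPM at the early post-activation stage).
#' @param p_threshold Bonferroni-corrected significance cutoff, default
#'   0.001.
#' @return tibble with one row per microRNA: `mature_id`, `min_down_p`,
#'   `min_up_p`, `flagged`, `expression`, `neg_log10_p`.
#' @export
rank_mirnas <- function(enrichment, expression = NULL, p_threshold = 0.001) {
  min_or_one <- function(x) if (length(x)) min(x) else 1
  out <- enrichment %>%
    dplyr::group_by(.data$mature_id) %>%
    dplyr::summarise(
      min_down_p = min_or_one(
        .data$p_bonferroni[startsWith(.data$set_label, "down")]),
      min_up_p = min_or_one(
        .data$p_bonferroni[startsWith(.data$set_label, "up")]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(flagged = .data$min_down_p < p_threshold &
                    .data$min_up_p >= p_threshold,
                  neg_log10_p = -log10(.data$min_down_p))
  if (!is.null(expression)) {
    out <- dplyr::left_join(out, expression, by = "mature_id")
  }
  dplyr::arrange(out, dplyr::desc(.data$neg_log10_p))
}
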