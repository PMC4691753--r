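## mirna_catalog: genomic clustering of microRNA hairpins and seed
## extraction / seed-family grouping.

#' Cluster microRNA loci within a genomic distance
#'
#' Single-linkage chaining per chromosome: consecutive hairpins whose
#' nearest boundaries (end of one to start of the next) are at most
#' `max_gap` apart join the same cluster. Strand is ignored; the result is
#' a partition of the loci and is invariant to input order.
#'
#' @param loci tibble with at least `locus_id`, `chrom`, `hairpin_start`,
#'   `hairpin_end` (one row per mature arm is fine; hairpins are
#'   de-duplicated by `locus_id`).
#' @param max_gap maximum inter-locus distance in bases, default 10000
#'   (the conventional 10-kb clustering rule).
#' @return tibble with one row per hairpin: `locus_id`, `chrom`,
#'   `hairpin_start`, `hairpin_end`, `cluster_id` (`"<chrom>:c<k>"`),
#'   `cluster_size`.
#' @export
cluster_loci <- function(loci, max_gap = 10000) {
  hp <- loci %>%
    dplyr::distinct(.data$locus_id, .data$chrom,
                    .data$hairpin_start, .data$hairpin_end) %>%
    dplyr::arrange(.data$chrom, .data$hairpin_start, .data$locus_id)
  hp <- hp %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(
      gap = .data$hairpin_start - dplyr::lag(cummax(.data$hairpin_end)),
      new_cluster = is.na(.data$gap) | .data$gap > max_gap,
      cluster_idx = cumsum(.data$new_cluster),
      cluster_id = paste0(.data$chrom, ":c", .data$cluster_idx)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"gap", -"new_cluster", -"cluster_idx")
  hp %>%
    dplyr::add_count(.data$cluster_id, name = "cluster_size")
}

#' Extract the seed region of a mature microRNA
#'
#' The seed is nucleotides 2..k+1 of the mature sequence (1-based from the
#' 5' end), the primary determinant of canonical target pairing.
#'
#' @param mature_seq mature sequence(s), RNA or DNA alphabet.
#' @param k seed length, one of 6, 7 or 8.
#' @return RNA seed string(s) of length `k`.
#' @export
#' @examples
#' extract_seed("UAGUACGUUAUCGAUGGCAA", 6) # "AGUACG"
extract_seed <- function(mature_seq, k = 6) {
  if (!k %in% c(6, 7, 8)) abort("seed length k must be 6, 7 or 8")
  short <- nchar(mature_seq) < k + 1
  if (any(short)) {
    abort(sprintf("mature sequence too short for a %d-mer seed (need >= %d nt)",
                  k, k + 1))
  }
  as_rna(substr(mature_seq, 2, k + 1))
}

#' Group mature microRNAs into seed families
#'
#' Mature microRNAs sharing an identical k-mer seed form one family,
#' regardless of similarity elsewhere in the sequence.
#'
#' @param matures tibble with `mature_id` and `mature_seq`.
#' @param k seed length (6, 7 or 8).
#' @return tibble with one row per family: `seed`, `n_members`, `members`
#'   (list-column of mature ids, lexicographic), ordered by seed.
#' @export
seed_families <- function(matures, k = 6) {
  matures %>%
    dplyr::mutate(seed = extract_seed(.data$mature_seq, k)) %>%
    dplyr::group_by(.data$seed) %>%
    dplyr::summarise(n_members = dplyr::n(),
                     members = list(sort(.data$mature_id)),
                     .groups = "drop") %>%
    dplyr::arrange(.data$seed)
}
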