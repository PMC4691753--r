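## target_prediction: canonical seed-match site discovery over merged
## per-gene 3' UTRs.
##
## Site classes, for a mature microRNA with seed s = positions 2..7 and
## m8 = position 8 (U == T):
##   6mer     revcomp(s)
##   7mer-A1  revcomp(s) followed by "A" in the target
##   7mer-m8  revcomp(positions 2..8)
##   8mer     revcomp(positions 2..8) followed by "A"
## Every canonical site contains the 6mer core revcomp(s); occurrences are
## found by scanning for that core and then resolved to their highest class
## by inspecting the flanking bases (8mer > 7mer-m8 > 7mer-A1 > 6mer).

#' Merge per-transcript 3' UTRs into one record per gene
#'
#' Genes with a single (or only duplicated) UTR keep it unchanged; distinct
#' UTRs are concatenated with an 8-N spacer so that no seed site can span
#' the junction (N never matches).
#'
#' @param utrs tibble with columns `gene`, `transcript`, `utr_seq`.
#' @param spacer string inserted between distinct UTRs of one gene.
#' @return tibble with one row per gene: `gene`, `utr_seq`,
#'   `n_transcripts`, `transcripts` (list-column). Genes whose UTRs are all
#'   empty are excluded; their ids are reported in attribute `excluded` and
#'   a warning.
#' @export
merge_utrs <- function(utrs, spacer = strrep("N", 8)) {
  utrs <- dplyr::mutate(utrs, utr_seq = as_dna(.data$utr_seq))
  merged <- utrs %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      utr_seq = paste(unique(.data$utr_seq[nchar(.data$utr_seq) > 0]),
                      collapse = spacer),
      n_transcripts = dplyr::n(),
      transcripts = list(sort(.data$transcript)),
      .groups = "drop"
    )
  empty <- merged$gene[nchar(merged$utr_seq) == 0]
  if (length(empty)) {
    warn(paste0("gene(s) with all-empty UTRs excluded: ",
                paste(empty, collapse = ", ")))
    merged <- dplyr::filter(merged, nchar(.data$utr_seq) > 0)
  }
  attr(merged, "excluded") <- empty
  merged
}

## the four class-defining site strings for one mature sequence
site_patterns <- function(mature_seq) {
  m <- as_dna(mature_seq)
  if (nchar(m) < 9) abort("mature sequence must be at least 9 nt for site patterns")
  seed6 <- substr(m, 2, 7)
  seed7 <- substr(m, 2, 8)
  core <- revcomp(seed6)
  list(core = core,
       m8_comp = complement_base(substr(m, 8, 8)),
       `6mer` = core,
       `7mer-A1` = paste0(core, "A"),
       `7mer-m8` = revcomp(seed7),
       `8mer` = paste0(revcomp(seed7), "A"))
}

#' Find canonical seed-match sites of mature microRNAs in 3' UTRs
#'
#' Scans each UTR 5'->3' for the 6mer seed core of each mature microRNA
#' and reports each occurrence once, resolved to its highest class
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer). The reported offset is the 0-based
#' position of the site string's 5' end (one before the core for classes
#' that pair position 8).
#'
#' @param matures tibble with `mature_id`, `mature_seq` (length >= 9).
#' @param utrs tibble with `gene`, `utr_seq` (merged records from
#'   [merge_utrs()] are the usual input).
#' @return tibble of sites: `gene`, `mature_id`, `class`, `offset`.
#' @export
find_sites <- function(matures, utrs) {
  pats <- purrr::map(setNames(matures$mature_seq, matures$mature_id),
                     site_patterns)
  rows <- purrr::imap(pats, function(p, mid) {
    core_hits <- stringi::stri_locate_all_fixed(utrs$utr_seq, p$core,
                                                overlap = TRUE)
    purrr::imap(core_hits, function(loc, gi) {
      starts <- loc[, 1]
      starts <- starts[!is.na(starts)]
      if (length(starts) == 0L) return(NULL)
      utr <- utrs$utr_seq[gi]
      n <- nchar(utr)
      before <- ifelse(starts > 1, substring(utr, starts - 1, starts - 1), "")
      after <- ifelse(starts + 6 <= n, substring(utr, starts + 6, starts + 6), "")
      has_m8 <- before == p$m8_comp
      has_a1 <- after == "A"
      class <- dplyr::case_when(
        has_m8 & has_a1 ~ "8mer",
        has_m8 ~ "7mer-m8",
        has_a1 ~ "7mer-A1",
        TRUE ~ "6mer"
      )
      offset <- ifelse(has_m8, starts - 2L, starts - 1L)  # 0-based site 5' end
      tibble(gene = utrs$gene[gi], mature_id = mid,
             class = class, offset = as.integer(offset))
    }) %>% purrr::compact() %>% dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(gene = character(), mature_id = character(),
                  class = character(), offset = integer()))
  }
  dplyr::arrange(out, .data$mature_id, .data$gene, .data$offset)
}

#' Predict gene-level microRNA targets from canonical sites
#'
#' A gene is called a target of a mature microRNA when it carries at least
#' one site of class `min_class` or better. The pair table reports
#' per-class site counts and the best class observed.
#'
#' @param matures,utrs as in [find_sites()].
#' @param min_class weakest class that counts toward targeting; default
#'   `"7mer-A1"` (7mers and 8mers count, lone 6mers do not). Use `"6mer"`
#'   to include all canonical classes.
#' @param sites optional precomputed site table from [find_sites()].
#' @return tibble of target pairs: `gene`, `mature_id`, `n_6mer`,
#'   `n_7mer_A1`, `n_7mer_m8`, `n_8mer`, `n_sites_counted`, `best_class`;
#'   ordered by `mature_id`, `gene`. Attribute `min_class` records the
#'   threshold.
#' @export
predict_targets <- function(matures, utrs, min_class = "7mer-A1",
                            sites = NULL) {
  if (!min_class %in% SITE_CLASSES) {
    abort(paste0("min_class must be one of: ", paste(SITE_CLASSES, collapse = ", ")))
  }
  sites <- sites %||% find_sites(matures, utrs)
  min_rank <- site_class_rank(min_class)
  if (nrow(sites) == 0L) {
    out <- tibble(gene = character(), mature_id = character(),
                  n_6mer = integer(), n_7mer_A1 = integer(),
                  n_7mer_m8 = integer(), n_8mer = integer(),
                  n_sites_counted = integer(), best_class = character())
    attr(out, "min_class") <- min_class
    return(out)
  }
  pairs <- sites %>%
    dplyr::group_by(.data$gene, .data$mature_id) %>%
    dplyr::summarise(
      n_6mer = sum(.data$class == "6mer"),
      n_7mer_A1 = sum(.data$class == "7mer-A1"),
      n_7mer_m8 = sum(.data$class == "7mer-m8"),
      n_8mer = sum(.data$class == "8mer"),
      n_sites_counted = sum(site_class_rank(.data$class) >= min_rank),
      best_class = SITE_CLASSES[max(site_class_rank(.data$class))],
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_sites_counted >= 1L) %>%
    dplyr::arrange(.data$mature_id, .data$gene)
  attr(pairs, "min_class") <- min_class
  pairs
}
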