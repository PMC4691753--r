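## read_mapping: exhaustive short-read alignment with best-stratum reporting,
## multi-map-corrected microRNA counting, and RPM normalization.
##
## The mapping policy mirrors a common small-RNA bowtie invocation
## (-v <mm> -a --best --strata -m <max_loci>): report every hit in the best
## mismatch stratum, discard reads hitting more than max_loci places, and
## split a retained multi-mapper's count equally across its hits.

#' Map one read against a toy genome, best mismatch stratum only
#'
#' Scans both strands of every chromosome for matches with at most
#' `max_mismatches` substitutions (no indels), then keeps only hits in the
#' best stratum: if any 0-mismatch hit exists only 0-mismatch hits are
#' reported, and so on. Reverse-strand hits report the genomic interval of
#' the reverse-complement match. `N` in the genome never matches a read base.
#'
#' @param genome named character vector (or `DNAStringSet`) of uppercase
#'   chromosome sequences.
#' @param seq read sequence (DNA or RNA alphabet; `U` is read as `T`).
#' @param max_mismatches maximum substitutions allowed (bowtie `-v`), default 1.
#' @return tibble with one row per hit: `chrom`, `strand`, `start` (0-based),
#'   `end` (half-open), `mismatches`. Zero rows if the read does not map.
#' @export
#' @examples
#' g <- c(chr1 = "ACGTACGTACGTACGTACGTACGT")
#' map_read(g, "ACGTACGTACGTACGTACGT", max_mismatches = 0)
map_read <- function(genome, seq, max_mismatches = 1) {
  gss <- if (is(genome, "DNAStringSet")) genome else genome_stringset(genome)
  read <- normalize_read(seq)
  pat_f <- Biostrings::DNAString(read)
  pat_r <- Biostrings::reverseComplement(pat_f)
  w <- nchar(read)

  out <- vector("list", 2L * length(gss))
  k <- 0L
  for (i in seq_along(gss)) {
    subj <- gss[[i]]
    nm <- names(gss)[i]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_f else pat_r
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatches,
                                    with.indels = FALSE, fixed = TRUE)
      st <- IRanges::start(m)
      keep <- st >= 1L & (st + w - 1L) <= length(subj)
      st <- st[keep]
      if (length(st) == 0L) next
      mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st,
                                        with.indels = FALSE, fixed = TRUE)
      k <- k + 1L
      out[[k]] <- tibble(chrom = nm, strand = strand,
                         start = st - 1L, end = st - 1L + w,
                         mismatches = as.integer(mm))
    }
  }
  hits <- if (k == 0L) {
    tibble(chrom = character(), strand = character(),
           start = integer(), end = integer(), mismatches = integer())
  } else {
    dplyr::bind_rows(out[seq_len(k)])
  }
  if (nrow(hits) > 0L) {
    hits <- dplyr::filter(hits, .data$mismatches == min(.data$mismatches))
    hits <- dplyr::arrange(hits, .data$chrom, .data$start, .data$strand)
  }
  hits
}

## read 5' anchor position of an alignment on its strand
hit_five_prime <- function(strand, start, end) {
  ifelse(strand == "+", start, end)
}

## assign one alignment to mature arms: contained in the hairpin (with the
## same slack tolerance on the boundaries, so that reads carrying short
## 3' additions that still align are not orphaned when a mature arm ends
## exactly at the hairpin boundary), 5' start within +/- anchor_slack of
## the annotated mature 5' end, same strand
assign_hit_to_matures <- function(hit, arms, anchor_slack = 3L) {
  cand <- arms[arms$chrom == hit$chrom & arms$strand == hit$strand, , drop = FALSE]
  if (nrow(cand) == 0L) return(character(0))
  contained <- hit$start >= cand$hairpin_start - anchor_slack &
    hit$end <= cand$hairpin_end + anchor_slack
  five_read <- if (hit$strand == "+") hit$start else hit$end
  five_mat <- ifelse(cand$strand == "+", cand$mature_start, cand$mature_end)
  anchored <- abs(five_read - five_mat) <= anchor_slack
  cand$mature_id[contained & anchored]
}

#' Quantify a collapsed small-RNA library against annotated microRNA loci
#'
#' Maps every unique read, discards reads hitting more than `max_loci`
#' genomic places, and adds `count / n_hits` to each mature microRNA a hit
#' is assigned to. A hit is assigned to a mature arm when the alignment is
#' contained in the hairpin and its 5' start lies within `anchor_slack`
#' nucleotides of the annotated mature 5' end.
#'
#' @param reads tibble with columns `seq` and `count` (collapsed library).
#' @param genome named character vector of chromosome sequences.
#' @param loci mature-arm annotation tibble as produced by
#'   [simulate_dataset()] / [read_loci_gff3()]: one row per mature arm with
#'   columns `mature_id`, `chrom`, `strand`, `hairpin_start`, `hairpin_end`,
#'   `mature_start`, `mature_end`.
#' @param max_mismatches bowtie-style `-v` mismatch allowance, default 1.
#' @param max_loci discard reads with more hits than this (bowtie `-m`),
#'   default 5.
#' @param min_read_len reads must be longer than 16 nt; shorter reads are
#'   dropped before mapping.
#' @param anchor_slack tolerance (nt) on the 5'-end anchor rule, default 3.
#' @param exclude optional tibble of intervals (`chrom`, `start`, `end`,
#'   0-based half-open) standing in for an abundant-RNA (e.g. tRNA) filter:
#'   reads with any best-stratum hit overlapping an interval are removed
#'   from the library before counting.
#' @return tibble with one row per mature arm: `mature_id`, `count`
#'   (fractional, multi-map corrected). Attributes `mapped_total`,
#'   `discarded_multi`, `unmapped` and `excluded` carry the per-library
#'   bookkeeping.
#' @export
quantify_library <- function(reads, genome, loci,
                             max_mismatches = 1, max_loci = 5,
                             min_read_len = 17, anchor_slack = 3,
                             exclude = NULL) {
  arms <- loci
  counts <- setNames(numeric(nrow(arms)), arms$mature_id)
  mapped_total <- 0
  discarded <- 0
  unmapped <- 0
  excluded <- 0
  gss <- genome_stringset(genome)
  hits_excluded <- function(hits) {
    if (is.null(exclude) || nrow(hits) == 0L) return(FALSE)
    for (h in seq_len(nrow(hits))) {
      ov <- exclude$chrom == hits$chrom[h] &
        exclude$start < hits$end[h] & exclude$end > hits$start[h]
      if (any(ov)) return(TRUE)
    }
    FALSE
  }

  if (nrow(reads) > 0) {
    reads <- dplyr::filter(reads, nchar(.data$seq) >= min_read_len)
  }
  if (nrow(reads) > 0) {
    for (j in seq_len(nrow(reads))) {
      seq <- reads$seq[j]
      cnt <- reads$count[j]
      hits <- map_read(gss, seq, max_mismatches = max_mismatches)
      n <- nrow(hits)
      if (n == 0L) {
        unmapped <- unmapped + cnt
      } else if (hits_excluded(hits)) {
        excluded <- excluded + cnt
      } else if (n > max_loci) {
        discarded <- discarded + cnt
      } else {
        mapped_total <- mapped_total + cnt
        for (h in seq_len(n)) {
          ids <- assign_hit_to_matures(hits[h, ], arms, anchor_slack)
          if (length(ids)) counts[ids] <- counts[ids] + cnt / n
        }
      }
    }
  }
  out <- tibble(mature_id = arms$mature_id, count = unname(counts))
  attr(out, "mapped_total") <- mapped_total
  attr(out, "discarded_multi") <- discarded
  attr(out, "unmapped") <- unmapped
  attr(out, "excluded") <- excluded
  out
}

#' Build a microRNA-by-library count matrix from collapsed libraries
#'
#' @param libraries named list of collapsed read tibbles (`seq`, `count`);
#'   names become library ids.
#' @param genome,loci,... passed to [quantify_library()].
#' @return a `mir_counts` tibble: `mature_id` plus one numeric column per
#'   library; attribute `totals` holds per-library genome-mapped totals and
#'   attribute `summary` a per-library mapping bookkeeping tibble.
#' @export
count_matrix <- function(libraries, genome, loci, ...) {
  stopifnot(length(libraries) > 0, !is.null(names(libraries)))
  cols <- purrr::imap(libraries, function(reads, nm) {
    quantify_library(reads, genome, loci, ...)
  })
  out <- tibble(mature_id = cols[[1]]$mature_id)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]$count
  totals <- vapply(cols, function(x) attr(x, "mapped_total"), numeric(1))
  attr(out, "totals") <- totals
  attr(out, "summary") <- tibble(
    library = names(cols),
    mapped = totals,
    discarded_multi = vapply(cols, function(x) attr(x, "discarded_multi"), numeric(1)),
    unmapped = vapply(cols, function(x) attr(x, "unmapped"), numeric(1)),
    excluded = vapply(cols, function(x) attr(x, "excluded"), numeric(1))
  )
  class(out) <- c("mir_counts", class(out))
  out
}

#' Reads-per-million normalization of a count matrix
#'
#' Each entry is scaled to reads per million genome-mapped reads in its
#' library: `count * 1e6 / library_total`.
#'
#' @param counts a `mir_counts` tibble from [count_matrix()], or a plain
#'   tibble with `mature_id` plus count columns and `totals` supplied.
#' @param totals optional named vector of per-library genome-mapped totals;
#'   defaults to the `totals` attribute.
#' @return tibble of the same shape with RPM values.
#' @export
rpm <- function(counts, totals = NULL) {
  totals <- totals %||% attr(counts, "totals")
  if (is.null(totals)) abort("rpm() needs per-library totals (attribute or argument)")
  libs <- setdiff(names(counts), "mature_id")
  missing <- setdiff(libs, names(totals))
  if (length(missing)) abort(paste0("no mapped total for library: ", missing[1]))
  zero <- libs[totals[libs] <= 0]
  if (length(zero)) {
    abort(paste0("library has zero genome-mapped reads: ", paste(zero, collapse = ", ")))
  }
  out <- counts
  for (lib in libs) out[[lib]] <- counts[[lib]] * 1e6 / totals[[lib]]
  out
}
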