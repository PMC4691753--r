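## tail_analysis: iterative 3'-trimming detection of nontemplated 3'-end
## nucleotide additions, and library-level tailing summaries (modified
## fraction, tail-length histogram, positional composition).

#' Call a nontemplated 3' tail on one read by iterative trimming
#'
#' If the full read maps to the genome with 0 mismatches it is `untailed`.
#' Otherwise one nucleotide is trimmed from the 3' end and the read is
#' remapped, repeating until a perfect hit is found (a `tailed` call whose
#' templated prefix is the longest perfectly mapping prefix) or the
#' remaining prefix would be shorter than `min_prefix` (`unmapped`).
#'
#' Only additions that differ from the genomic sequence immediately 3' of
#' the mapped prefix are observable: a tail that continues the template is
#' absorbed into the prefix, so reported modification rates are
#' conservative.
#'
#' @param genome named character vector of chromosome sequences.
#' @param read read sequence.
#' @param min_prefix shortest templated prefix considered mappable,
#'   default 16.
#' @return one-row tibble: `seq`, `status` (`untailed`/`tailed`/`unmapped`),
#'   `prefix_len`, `tail` (empty string when untailed), and a `hits`
#'   list-column with the best-stratum hits of the mapped prefix.
#' @export
call_tail <- function(genome, read, min_prefix = 16) {
  gss <- if (is(genome, "DNAStringSet")) genome else genome_stringset(genome)
  read <- normalize_read(read)
  n <- nchar(read)
  len <- n
  while (len >= min_prefix) {
    prefix <- substr(read, 1L, len)
    hits <- map_read(gss, prefix, max_mismatches = 0)
    if (nrow(hits) > 0L) {
      status <- if (len == n) "untailed" else "tailed"
      return(tibble(seq = read, status = status, prefix_len = len,
                    tail = substr(read, len + 1L, n), hits = list(hits)))
    }
    len <- len - 1L
  }
  tibble(seq = read, status = "unmapped", prefix_len = NA_integer_,
         tail = NA_character_, hits = list(tibble()))
}

#' Call tails for every read of a collapsed library
#'
#' Applies [call_tail()] to each unique read and, when `loci` are given,
#' assigns mapped reads to mature microRNAs with the same 5'-anchor rule
#' and fractional 1/n multi-map weighting used for counting.
#'
#' @param reads collapsed library tibble (`seq`, `count`).
#' @param genome named character vector of chromosome sequences.
#' @param loci optional mature-arm annotation (see [quantify_library()]).
#' @param min_prefix passed to [call_tail()].
#' @param anchor_slack 5'-anchor tolerance for mature assignment.
#' @return tibble at read-by-assignment grain: `seq`, `count`, `status`,
#'   `prefix_len`, `tail`, `mature_id` (NA when unassigned or unmapped) and
#'   `weight` (fraction of `count` carried by the row).
#' @export
call_tails <- function(reads, genome, loci = NULL, min_prefix = 16,
                       anchor_slack = 3) {
  gss <- genome_stringset(genome)
  rows <- purrr::pmap(list(reads$seq, reads$count), function(seq, count) {
    call <- call_tail(gss, seq, min_prefix = min_prefix)
    hits <- call$hits[[1]]
    base <- tibble(seq = call$seq, count = count, status = call$status,
                   prefix_len = call$prefix_len, tail = call$tail)
    if (is.null(loci) || nrow(hits) == 0L) {
      base$mature_id <- NA_character_
      base$weight <- 1
      return(base)
    }
    n <- nrow(hits)
    assigned <- purrr::map(seq_len(n), function(h) {
      assign_hit_to_matures(hits[h, ], loci, anchor_slack)
    })
    ids <- unlist(assigned)
    if (length(ids) == 0L) {
      base$mature_id <- NA_character_
      base$weight <- 1
      return(base)
    }
    out <- base[rep(1L, length(ids)), ]
    out$mature_id <- ids
    out$weight <- 1 / n
    ## hits assigned to no mature keep their weight on an NA row so that
    ## per-read weights still sum to 1
    n_unassigned <- sum(vapply(assigned, length, integer(1)) == 0L)
    if (n_unassigned > 0L) {
      na_row <- base
      na_row$mature_id <- NA_character_
      na_row$weight <- n_unassigned / n
      out <- dplyr::bind_rows(out, na_row)
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Summarize tail calls: modified fractions, lengths, composition
#'
#' Proportions are count-weighted: a collapsed read with count c and
#' multi-map weight w contributes c*w. The positional composition matrix
#' covers the first five tail positions; longer tails are recorded in the
#' histogram but only their first five positions enter the matrix.
#'
#' @param calls tibble from [call_tails()].
#' @param max_positions number of tail positions in the composition matrix.
#' @return object of class `tail_summary`: a list with `overall` (one-row
#'   tibble: weighted modified/unmodified/unmapped counts and
#'   `modified_proportion`), `per_mature`, `length_hist` (tibble `tail_len`,
#'   `weight`) and `composition` (tibble `position`, `A`,`C`,`G`,`T`,
#'   row-normalised; rows with no observations are NA).
#' @export
summarize_tails <- function(calls, max_positions = 5) {
  calls <- dplyr::mutate(calls, w = .data$count * .data$weight)
  overall <- calls %>%
    dplyr::summarise(
      modified = sum(.data$w[.data$status == "tailed"]),
      unmodified = sum(.data$w[.data$status == "untailed"]),
      unmapped = sum(.data$w[.data$status == "unmapped"])
    ) %>%
    dplyr::mutate(modified_proportion = ifelse(
      .data$modified + .data$unmodified > 0,
      .data$modified / (.data$modified + .data$unmodified), NA_real_))

  per_mature <- calls %>%
    dplyr::filter(!is.na(.data$mature_id), .data$status != "unmapped") %>%
    dplyr::group_by(.data$mature_id) %>%
    dplyr::summarise(
      modified = sum(.data$w[.data$status == "tailed"]),
      unmodified = sum(.data$w[.data$status == "untailed"]),
      total = modified + unmodified,
      modified_proportion = ifelse(total > 0, modified / total, NA_real_),
      .groups = "drop"
    )

  ## de-duplicate multi-assignment rows: tails are per read, so histogram
  ## and composition weight each read by count (weights within a read sum
  ## to 1 across its assignment rows)
  tails <- calls %>%
    dplyr::filter(.data$status == "tailed") %>%
    dplyr::group_by(.data$seq, .data$tail) %>%
    dplyr::summarise(w = sum(.data$w), .groups = "drop")

  if (nrow(tails) > 0) {
    length_hist <- tails %>%
      dplyr::mutate(tail_len = nchar(.data$tail)) %>%
      dplyr::group_by(.data$tail_len) %>%
      dplyr::summarise(weight = sum(.data$w), .groups = "drop") %>%
      dplyr::arrange(.data$tail_len)
  } else {
    length_hist <- tibble(tail_len = integer(), weight = numeric())
  }

  comp <- matrix(0, nrow = max_positions, ncol = 4,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  if (nrow(tails) > 0) {
    for (i in seq_len(nrow(tails))) {
      tl <- tails$tail[i]
      for (p in seq_len(min(nchar(tl), max_positions))) {
        b <- substr(tl, p, p)
        if (b %in% colnames(comp)) comp[p, b] <- comp[p, b] + tails$w[i]
      }
    }
  }
  rs <- rowSums(comp)
  comp_norm <- comp / ifelse(rs > 0, rs, NA_real_)
  composition <- as_tibble(comp_norm) %>%
    dplyr::mutate(position = dplyr::row_number(), observed = rs > 0) %>%
    dplyr::relocate("position")

  structure(list(overall = overall, per_mature = per_mature,
                 length_hist = length_hist, composition = composition),
            class = "tail_summary")
}

#' @export
print.tail_summary <- function(x, ...) {
  cat("<tail_summary>\n")
  cat(sprintf("  modified proportion: %.4f (%g modified / %g mapped)\n",
              x$overall$modified_proportion,
              x$overall$modified, x$overall$modified + x$overall$unmodified))
  cat(sprintf("  matures summarised: %d\n", nrow(x$per_mature)))
  invisible(x)
}

#' @rdname summarize_tails
#' @param x a `tail_summary`.
#' @param ... unused.
#' @export
tidy.tail_summary <- function(x, ...) x$per_mature

#' @rdname summarize_tails
#' @export
glance.tail_summary <- function(x, ...) x$overall
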