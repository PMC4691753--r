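## Sequence utilities shared across modules. Sequences are plain uppercase
## character vectors; DNA internally (U and T interchangeable on input).

SITE_CLASSES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Convert a nucleotide string to uppercase DNA (U -> T)
#'
#' @param x character vector of sequences (DNA or RNA alphabet).
#' @return uppercase DNA character vector.
#' @export
as_dna <- function(x) {
  x <- chartr("u", "U", toupper(x))
  chartr("U", "T", x)
}

#' Convert a nucleotide string to uppercase RNA (T -> U)
#' @param x character vector of sequences.
#' @return uppercase RNA character vector.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement of DNA sequences
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", as_dna(x)))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

## validate read alphabet: ACGTUN only (case-insensitive); returns DNA form
normalize_read <- function(seq, what = "read") {
  seq <- toupper(seq)
  bad <- stringr::str_detect(seq, "[^ACGTUN]")
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGTUN characters: %s",
                  what, paste(head(seq[bad], 3), collapse = ", ")))
  }
  as_dna(seq)
}

## genome: named uppercase DNA character vector; also accepts DNAStringSet
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (is.null(names(genome)) || anyDuplicated(names(genome))) {
    abort("genome must be a named vector (or DNAStringSet) with unique chromosome names")
  }
  g <- toupper(genome)
  bad <- stringr::str_detect(g, "[^ACGTN]")
  if (any(bad)) abort("genome alphabet must be A/C/G/T/N")
  g
}

## cached DNAStringSet view of a genome for Biostrings matching
genome_stringset <- function(genome) {
  Biostrings::DNAStringSet(as_genome(genome))
}

site_class_rank <- function(class) {
  match(class, SITE_CLASSES)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Percentage of annotated genes detected, rounded to the printed integer
#'
#' Small reporting helper used when summarising transcriptome detection
#' (at least one fragment observed) against an annotation.
#'
#' @param n_detected number of genes with evidence of expression.
#' @param n_annotated number of annotated genes.
#' @return integer percentage, rounded.
#' @export
detection_percent <- function(n_detected, n_annotated) {
  stopifnot(n_annotated > 0, n_detected >= 0, n_detected <= n_annotated)
  round(100 * n_detected / n_annotated)
}
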