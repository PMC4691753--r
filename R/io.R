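## File formats: genome FASTA, loci GFF3 (pre_miRNA/miRNA features),
## collapsed reads FASTA with counts in the identifier ("id_xN"), spike-in
## and DE tables as TSV, UTR FASTA keyed by gene id, truth as JSON.

#' Write / read a genome FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path file path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_genome(genome)), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  setNames(as.character(ss), names(ss))
}

#' Write / read a collapsed small-RNA library FASTA
#'
#' Reads are stored one record per unique sequence with the collapsed
#' count encoded in the identifier (`id_xN` dialect).
#'
#' @param reads tibble with `seq` and `count`.
#' @param path file path.
#' @export
write_collapsed_fasta <- function(reads, path) {
  ids <- sprintf("r%06d_x%d", seq_len(nrow(reads)),
                 as.integer(round(reads$count)))
  ss <- Biostrings::DNAStringSet(as_dna(reads$seq))
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_collapsed_fasta
#' @export
read_collapsed_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  counts <- suppressWarnings(as.numeric(sub("^.*_x(\\d+)\\s*$", "\\1",
                                            names(ss))))
  if (anyNA(counts)) abort("collapsed FASTA identifiers must end in _x<count>")
  tibble(seq = unname(as.character(ss)), count = counts)
}

#' Write / read microRNA loci as GFF3
#'
#' Hairpins are `pre_miRNA` features and mature arms `miRNA` features with
#' a `Parent` attribute; coordinates are converted between the package's
#' 0-based half-open convention and GFF3's 1-based closed one.
#'
#' @param loci per-arm loci tibble (see [simulate_dataset()]).
#' @param path file path.
#' @export
write_loci_gff3 <- function(loci, path) {
  hp <- dplyr::distinct(loci, .data$locus_id, .data$chrom, .data$strand,
                        .data$hairpin_start, .data$hairpin_end)
  gr_hp <- GenomicRanges::GRanges(
    seqnames = hp$chrom,
    ranges = IRanges::IRanges(start = hp$hairpin_start + 1, end = hp$hairpin_end),
    strand = hp$strand, type = "pre_miRNA", ID = hp$locus_id)
  gr_m <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$mature_start + 1, end = loci$mature_end),
    strand = loci$strand, type = "miRNA", ID = loci$mature_id,
    Parent = loci$locus_id)
  rtracklayer::export(c(gr_hp, gr_m), path, format = "gff3")
  invisible(path)
}

#' @rdname write_loci_gff3
#' @param genome optional genome used to fill in mature sequences.
#' @export
read_loci_gff3 <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  hp <- df[df$type == "pre_miRNA", ]
  mm <- df[df$type == "miRNA", ]
  parent <- vapply(mm$Parent, function(p) as.character(p)[1], character(1))
  out <- tibble(
    locus_id = parent,
    mature_id = mm$ID,
    arm = ifelse(grepl("-5p$", mm$ID), "5p",
                 ifelse(grepl("-3p$", mm$ID), "3p", NA_character_)),
    chrom = as.character(mm$seqnames),
    strand = as.character(mm$strand),
    hairpin_start = hp$start[match(parent, hp$ID)] - 1L,
    hairpin_end = hp$end[match(parent, hp$ID)],
    mature_start = mm$start - 1L,
    mature_end = mm$end
  )
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    out$mature_seq <- as_rna(vapply(seq_len(nrow(out)), function(i) {
      substr(genome[[out$chrom[i]]], out$mature_start[i] + 1, out$mature_end[i])
    }, character(1)))
  }
  out
}

#' Write / read spike-in definitions as TSV
#' @param spikes tibble with at least `spike_id`, `seq`, `fmol`.
#' @param path file path.
#' @export
write_spikes_tsv <- function(spikes, path) {
  readr::write_tsv(spikes, path)
  invisible(path)
}

#' @rdname write_spikes_tsv
#' @export
read_spikes_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read merged 3' UTRs as FASTA keyed by gene id
#' @param utrs tibble with `gene`, `utr_seq`.
#' @param path file path.
#' @export
write_utr_fasta <- function(utrs, path) {
  ss <- Biostrings::DNAStringSet(as_dna(utrs$utr_seq))
  names(ss) <- utrs$gene
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_utr_fasta
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(gene = sub("\\s.*$", "", names(ss)),
         utr_seq = unname(as.character(ss)))
}

#' Write / read a differential-expression table (gene, log2fc, padj) as TSV
#' @param de tibble with `gene`, `log2fc`, `padj`.
#' @param path file path.
#' @export
write_de_tsv <- function(de, path) {
  readr::write_tsv(de, path)
  invisible(path)
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a whole synthetic dataset to a directory
#'
#' Emits `genome.fa`, `loci.gff3`, `reads_<stage>.fa`, `spikes.tsv`,
#' `utrs.fa`, `de_<comparison>.tsv` and `truth.json`.
#'
#' @param sim a `mir_sim` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the paths written.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                loci = file.path(dir, "loci.gff3"),
                spikes = file.path(dir, "spikes.tsv"),
                utrs = file.path(dir, "utrs.fa"),
                truth = file.path(dir, "truth.json"))
  write_genome_fasta(sim$genome, paths$genome)
  write_loci_gff3(sim$loci, paths$loci)
  write_spikes_tsv(sim$spikes, paths$spikes)
  write_utr_fasta(sim$utrs, paths$utrs)
  for (stage in names(sim$libraries)) {
    p <- file.path(dir, paste0("reads_", stage, ".fa"))
    write_collapsed_fasta(sim$libraries[[stage]], p)
    paths[[paste0("reads_", stage)]] <- p
  }
  for (cmp in names(sim$de_tables)) {
    p <- file.path(dir, paste0("de_", cmp, ".tsv"))
    write_de_tsv(sim$de_tables[[cmp]], p)
    paths[[paste0("de_", cmp)]] <- p
  }
  truth <- sim$truth
  truth$reads <- purrr::map(truth$reads, as.data.frame)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
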