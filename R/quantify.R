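## quantification: absolute microRNA amounts from spike-in or endogenous
## references, unit conversion to molecule counts, and all-versus-all stage
## correlation of expression profiles.

AVOGADRO <- 6.02214076e23

#' Absolute microRNA quantification against a reference of known amount
#'
#' Treats all microRNA reads as equimolar per read and scales the total
#' read count by a reference species of known molar amount (a synthetic
#' spike-in, or an endogenous microRNA quantified independently):
#' `fmol_per_egg = total_reads / reference_reads * reference_fmol / n_eggs`.
#'
#' Vectorised over references; with several spike-ins each yields its own
#' estimate and the spread across references is the reported uncertainty.
#'
#' @param total_mirna_reads total microRNA-mapped read count of the library.
#' @param reference_reads read count(s) of the reference species.
#' @param reference_fmol known molar amount(s) of the reference, fmol per
#'   library.
#' @param n_eggs number of eggs pooled in the library.
#' @param reference label(s) for the reference used
#'   (`"spike-in"`/`"endogenous"`).
#' @return tibble with one row per reference: `reference`, `reference_fmol`,
#'   `reference_reads`, `fmol_per_egg`, `molecules_per_egg`, `n_eggs`.
#' @export
absolute_quantify <- function(total_mirna_reads, reference_reads,
                              reference_fmol, n_eggs = 1,
                              reference = "spike-in") {
  stopifnot(n_eggs > 0, all(reference_fmol > 0))
  if (any(reference_reads <= 0)) {
    abort("reference below detection: zero reference reads")
  }
  fmol <- total_mirna_reads / reference_reads * reference_fmol / n_eggs
  tibble(reference = reference,
         reference_fmol = reference_fmol,
         reference_reads = reference_reads,
         fmol_per_egg = fmol,
         molecules_per_egg = fmol_to_molecules(fmol),
         n_eggs = n_eggs)
}

#' Convert a molar amount in femtomoles to molecule counts
#'
#' @param fmol amount in fmol (non-negative).
#' @return number of molecules (`fmol * 1e-15 * Avogadro`).
#' @export
#' @examples
#' fmol_to_molecules(0.2) # ~1.2e8 molecules
fmol_to_molecules <- function(fmol) {
  if (any(fmol < 0)) abort("fmol must be non-negative")
  fmol * 1e-15 * AVOGADRO
}

#' All-versus-all correlation of library expression profiles
#'
#' Spearman rank correlation (average ranks on ties) between every pair of
#' libraries in a count matrix; the usual companion to a developmental
#' profile heat map.
#'
#' @param counts `mir_counts` tibble ([count_matrix()]) or any tibble with
#'   `mature_id` plus one numeric column per library.
#' @param method correlation method, default `"spearman"`.
#' @return correlation matrix (libraries x libraries) of class `stage_cor`;
#'   pairs involving a constant library are `NA` and flagged with a warning
#'   naming the library.
#' @export
stage_correlation <- function(counts, method = "spearman") {
  libs <- setdiff(names(counts), "mature_id")
  if (length(libs) < 2) abort("need at least 2 libraries")
  m <- as.matrix(as.data.frame(counts[libs]))
  const <- libs[apply(m, 2, function(x) length(unique(x)) == 1L)]
  if (length(const)) {
    warn(paste0("constant expression column(s), correlations undefined: ",
                paste(const, collapse = ", ")))
  }
  cc <- suppressWarnings(cor(m, method = method))
  diag(cc) <- 1
  cc[const, ] <- NA_real_
  cc[, const] <- NA_real_
  diag(cc)[colnames(cc) %in% const] <- NA_real_
  structure(cc, class = c("stage_cor", class(cc)))
}

#' @export
tidy.stage_cor <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal") %>%
    setNames(c("library1", "library2", "rho")) %>%
    dplyr::mutate(dplyr::across(c("library1", "library2"), as.character))
}
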