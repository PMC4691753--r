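## ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile geom_point
#'   geom_hline labs scale_fill_gradient2 facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Tail length distribution and positional composition
#'
#' @param object a `tail_summary` from [summarize_tails()].
#' @param ... unused.
#' @return a ggplot: count-weighted tail length histogram.
#' @export
autoplot.tail_summary <- function(object, ...) {
  ggplot(object$length_hist, aes(x = factor(.data$tail_len), y = .data$weight)) +
    geom_col(fill = "steelblue") +
    labs(x = "tail length (nt)", y = "weighted reads",
         title = "Nontemplated 3' tail lengths") +
    theme_minimal()
}

#' Positional nucleotide composition of recovered tails
#' @param summary a `tail_summary`.
#' @return a ggplot tile map of per-position base frequencies.
#' @export
plot_tail_composition <- function(summary) {
  comp <- summary$composition %>%
    tidyr::pivot_longer(c("A", "C", "G", "T"),
                        names_to = "base", values_to = "freq")
  ggplot(comp, aes(x = .data$position, y = .data$base, fill = .data$freq)) +
    geom_tile() +
    scale_fill_gradient2(low = "white", high = "darkred", limits = c(0, 1)) +
    labs(x = "tail position", y = NULL, fill = "frequency",
         title = "Tail nucleotide composition") +
    theme_minimal()
}

#' All-versus-all stage correlation heat map
#' @param object a `stage_cor` from [stage_correlation()].
#' @param ... unused.
#' @export
autoplot.stage_cor <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$library1, y = .data$library2,
                           fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         midpoint = 0, limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "rho",
         title = "Stage-to-stage expression correlation") +
    theme_minimal()
}

#' Expression versus target enrichment for clearance candidates
#'
#' @param clearance tibble from [rank_mirnas()] (with an `expression`
#'   column).
#' @param p_threshold horizontal reference line (Bonferroni cutoff).
#' @export
plot_clearance <- function(clearance, p_threshold = 0.001) {
  ggplot(clearance, aes(x = .data$expression, y = .data$neg_log10_p,
                        colour = .data$flagged)) +
    geom_point(size = 2) +
    geom_hline(yintercept = -log10(p_threshold), linetype = "dashed") +
    labs(x = "expression (RPM)", y = "-log10 Bonferroni p (down set)",
         colour = "flagged",
         title = "MicroRNA expression vs target enrichment") +
    theme_minimal()
}
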