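# ggplot2 views of the main result types.

#' Plot an exon-distance profile
#'
#' Per-intron density of conserved elements as a function of signed
#' distance from the closest exon boundary (negative: inside exons).
#'
#' @param object An `exon_distance_profile` from [exon_distance_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exon_distance_profile <- function(object, ...) {
  bw <- attr(object, "bin_width") %||% 100
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_start + bw / 2,
                                       y = .data$density,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance from closest exon boundary (bp)",
                  y = "elements per bin / introns in group",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot first-overlapping-repeat attribution
#'
#' Counts of repeat-overlapping conserved elements by the category of
#' their first overlapping repeat, per gene group.
#'
#' @param repeat_attribution Tibble `group`, `first_repeat_category`, `n`
#'   (see [analyze_bundle()]).
#' @return A ggplot object.
#' @export
plot_repeat_attribution <- function(repeat_attribution) {
  df <- repeat_attribution |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(frac = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$first_repeat_category,
                                   y = .data$frac, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "first overlapping repeat", y = "fraction of elements",
                  fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot element score and length distributions per class
#'
#' @param elements Classified element tibble.
#' @return A ggplot object (score vs length, faceted by class).
#' @export
plot_element_distributions <- function(elements) {
  df <- dplyr::mutate(elements, length = .data$end - .data$start)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$element_class)) +
    ggplot2::labs(x = "element length (bp)", y = "conservation score") +
    ggplot2::theme_minimal()
}

#' Plot motif enrichment scores
#'
#' Score against genomic background versus score against the comparison
#' collection, with the passing threshold marked.
#'
#' @param motifs Tibble from [enriched_motifs()].
#' @param threshold Threshold drawn on both axes (default 3.5).
#' @return A ggplot object.
#' @export
plot_motif_scores <- function(motifs, threshold = 3.5) {
  ggplot2::ggplot(motifs, ggplot2::aes(x = .data$score_vs_genome,
                                       y = .data$score_vs_comparison,
                                       colour = .data$contains_cpg)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "score vs genomic background", y = "score vs comparison",
                  colour = "contains CpG") +
    ggplot2::theme_minimal()
}
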