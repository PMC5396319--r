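#' Heatmap of a patient-by-pathway defective-gene matrix
#'
#' Tiles coloured by the per-cell defective-gene count, with the count
#' printed in each cell; pathways ordered as selected (per-pathway total,
#' ties lexicographic).
#'
#' @param object a [pathway_matrix()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_matrix <- function(object, ...) {
  cells <- object$cells
  cells$pathway_id <- factor(cells$pathway_id, levels = rev(object$pathways))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$sample_id,
                                      y = .data$pathway_id,
                                      fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey30") +
    ggplot2::labs(x = "patient", y = NULL, fill = "defective\ngenes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Enrichment dot plot
#'
#' Pathways against -log10 enrichment p-value, significant pathways
#' (p < 0.05, unadjusted) highlighted.
#'
#' @param object a `crlf2_enrichment` from [enrich_pathways()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.crlf2_enrichment <- function(object, ...) {
  res <- object$results
  res$pathway_id <- factor(res$pathway_id,
                           levels = rev(res$pathway_id[order(res$p_value)]))
  ggplot2::ggplot(res, ggplot2::aes(x = -log10(.data$p_value),
                                    y = .data$pathway_id,
                                    colour = .data$significant,
                                    size = .data$x)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  colour = "p < .05", size = "overlap",
                  title = paste0("Pathway enrichment: ", object$group_label)) +
    ggplot2::theme_minimal()
}

#' Grouped bar chart of subgroup lesion frequencies
#'
#' @param object a `lesion_comparison` from [compare_lesion_frequencies()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lesion_comparison <- function(object, ...) {
  res <- object$results
  long <- tidyr::pivot_longer(
    dplyr::select(res, "lesion", "freq_a", "freq_b", "p_value"),
    cols = c("freq_a", "freq_b"), names_to = "group", values_to = "freq")
  long$group <- ifelse(long$group == "freq_a", object$groups[[1]],
                       object$groups[[2]])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lesion, y = .data$freq,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = res[res$p_value < 0.05, , drop = FALSE],
      ggplot2::aes(x = .data$lesion, y = pmax(.data$freq_a, .data$freq_b) + 3,
                   label = "*"),
      inherit.aes = FALSE, size = 5) +
    ggplot2::labs(x = NULL, y = "patients with lesion (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Variant allele frequency distribution per patient
#'
#' Box-and-jitter of per-mutation VAF by sample, with the 30% reference line
#' used to judge clonality.
#'
#' @param mutations mutation tibble.
#' @return A ggplot object.
#' @export
plot_vaf_distribution <- function(mutations) {
  d <- mutations
  d$vaf <- vaf(d$alt_depth, d$total_depth)
  d <- d[!is.na(d$vaf), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$vaf)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.30, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "patient", y = "variant allele frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
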