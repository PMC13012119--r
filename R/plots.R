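#' Plot organ-enrichment calls as a grouped heatmap
#'
#' Mirrors the atlas heatmap: enriched genes as rows grouped by organ,
#' atlas (organ, stage) cells as columns, log10(RPKM + pseudocount) fill,
#' grey for unavailable measurements.
#'
#' @param object An `enrichment_calls` tibble.
#' @param atlas The `expr_atlas` the calls were produced from.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot enrichment_calls
#' @export
autoplot.enrichment_calls <- function(object, atlas, ...) {
  heat <- grouped_heatmap_table(object, atlas)
  long <- heat |>
    tidyr::pivot_longer(-c("gene", "organ"), names_to = "cell",
                        values_to = "rpkm") |>
    tidyr::separate("cell", into = c("col_organ", "stage"), sep = "\\|")
  long$gene <- factor(long$gene, levels = rev(heat$gene))
  long$cell <- factor(paste(long$col_organ, long$stage),
                      levels = unique(paste(long$col_organ, long$stage)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell, y = .data$gene,
                                     fill = log10(.data$rpkm + 0.1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80",
                                  name = "log10(RPKM + 0.1)") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$organ), scales = "free_y",
                        space = "free_y") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "enriched gene")
}

#' Plot the temporal screen: mean expression versus stage ratio
#'
#' @param object A `screen_candidates` tibble.
#' @param config The [screen_config()] used (defaults drawn as dashed
#'   threshold lines).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot screen_candidates
#' @export
autoplot.screen_candidates <- function(object, config = screen_config(), ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$ratio),
                      !is.na(.data$mean_rpkm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_rpkm, y = .data$ratio,
                                   colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = config$min_mean_rpkm, linetype = 2) +
    ggplot2::geom_hline(yintercept = config$min_ratio, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean RPKM", y = sprintf("%s / %s ratio",
                                               config$numerator_stage,
                                               config$denominator_stage)) +
    ggplot2::theme_minimal()
}

#' Plot term-enrichment results
#'
#' Top terms as a dot chart of -log10(q), dot size the overlap count.
#'
#' @param object An `enrich_results` tibble.
#' @param n_top Number of terms to display (default 10).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot enrich_results
#' @export
autoplot.enrich_results <- function(object, n_top = 10, ...) {
  df <- top_terms(object, n_top)
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q), y = .data$name,
                                   size = .data$k)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "-log10(q)", y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}

#' Plot a single-cell dot-plot summary
#'
#' Genes by stage, dot size the fraction of expressing cells, colour the
#' mean expression — the standard dot-plot encoding.
#'
#' @param object A `dotplot_summary` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot dotplot_summary
#' @export
autoplot.dotplot_summary <- function(object, ...) {
  df <- as_tibble(object)
  df$stage <- factor(df$stage, levels = unique(df$stage[order(
    stage_key_safe(df$stage))]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$gene,
                                   size = .data$fraction_expressing,
                                   colour = .data$mean_expression)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(max_size = 8, limits = c(0, 1)) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$species),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, size = "fraction expressing",
                  colour = "mean count") +
    ggplot2::theme_minimal()
}
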