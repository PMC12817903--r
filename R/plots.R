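# ggplot2 views of the main result types.

#' Plot a cutoff sweep
#'
#' AUC (solid line, right axis in spirit of the usual presentation) and the
#' number of ground-truth hits (shaded area, rescaled) against the CG score
#' cutoff, faceted by direction (and ground-truth library when present).
#' Cutoffs where the AUC is undefined are left blank.
#'
#' @param object A `sweep_result` from [cutoff_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  max_hits <- max(object$n_hits, 1)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$cutoff)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$n_hits / max_hits),
                       fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$auc), linewidth = 0.8,
                       na.rm = TRUE) +
    ggplot2::scale_y_continuous(
      name = "AUC",
      sec.axis = ggplot2::sec_axis(~ . * max_hits, name = "hits passing cutoff")) +
    ggplot2::labs(x = "|CG score| cutoff") +
    ggplot2::theme_minimal()
  if ("truth_library" %in% names(object)) {
    p + ggplot2::facet_grid(truth_library ~ direction)
  } else {
    p + ggplot2::facet_wrap(~direction)
  }
}

#' Volcano plot of protein differential abundance
#'
#' @param object A `protein_diff_stats` tibble from [protein_diff()].
#' @param lfc_cutoff,alpha Gates drawn as dashed lines (defaults 1, 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot protein_diff_stats
#' @export
autoplot.protein_diff_stats <- function(object, lfc_cutoff = 1, alpha = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lfc, y = -log10(.data$q),
                                       colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_cutoff, lfc_cutoff), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (treated vs control)",
                  y = "-log10 FDR", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Heatmap of normalized CG scores for hit genes
#'
#' Genes (rows) are ordered by Ward clustering; columns are condition x
#' library. Input is the `normalized` table of a `screen_result` (or any
#' tibble with `gene_id`, `condition`, `tn`, `crispri`).
#'
#' @param normalized Long tibble with columns `gene_id`, `condition`, `tn`,
#'   `crispri`.
#' @param genes Genes to display (default: all in the table).
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(normalized, genes = NULL) {
  genes <- genes %||% unique(normalized$gene_id)
  long <- normalized %>%
    dplyr::filter(.data$gene_id %in% genes) %>%
    tidyr::pivot_longer(c("tn", "crispri"), names_to = "library",
                        values_to = "cg_score") %>%
    dplyr::mutate(column = paste(.data$condition, .data$library, sep = "\n"))
  wide <- normalized %>%
    dplyr::filter(.data$gene_id %in% genes) %>%
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "condition",
                       values_from = c("tn", "crispri"), values_fill = 0)
  order_ids <- if (nrow(wide) >= 2) {
    hc <- ward_linkage(wide)
    wide$gene_id[hc$order]
  } else {
    wide$gene_id
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column,
                                     y = factor(.data$gene_id, levels = order_ids),
                                     fill = .data$cg_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "CG score") +
    ggplot2::theme_minimal()
}
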