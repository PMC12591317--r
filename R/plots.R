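#' Volcano plot of differential results
#'
#' One panel per comparison: log2 fold-change against -log10 raw p, with
#' discoveries (FDR and fold-change rules) highlighted.
#'
#' @param object a `phosdiff_stats` tibble from [analyze_features()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot phosdiff_stats
#' @export
autoplot.phosdiff_stats <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$raw_p))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$raw_p), colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 p",
                  colour = "discovery") +
    ggplot2::theme_minimal()
}

#' Kinase activity bar plot
#'
#' Kinase z-scores per comparison for kinases with at least the minimum
#' substrate count, significant ones filled.
#'
#' @param object a `phosdiff_ksea` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot phosdiff_ksea
#' @export
autoplot.phosdiff_ksea <- function(object, ...) {
  df <- dplyr::filter(object$scores,
                      .data$m >= object$params$ksea_min_substrates)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$z, y = stats::reorder(.data$kinase_id, .data$z),
    fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = "kinase activity z-score", y = NULL,
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' Normalized enrichment score per set, sized by set size, coloured by
#' FDR.
#'
#' @param object a `phosdiff_gsea` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot phosdiff_gsea
#' @export
autoplot.phosdiff_gsea <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$nes, y = stats::reorder(.data$set_name, .data$nes),
    size = .data$size, colour = .data$fdr
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "firebrick", high = "grey70") +
    ggplot2::labs(x = "normalized enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Specificity count bar plot
#'
#' @param summary tibble from [summarize_specificity()].
#' @return A ggplot object.
#' @export
plot_specificity_counts <- function(summary) {
  df <- dplyr::filter(summary, .data$type != "union")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, .data$n), y = .data$n,
    fill = .data$type
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "alteration-specific features",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
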