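#' @export
ggplot2::autoplot

#' Plot the permutation null histogram with the observed pair count
#' @param object A `pair_permutation` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pair_permutation
#' @export
autoplot.pair_permutation <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = pairs, y = n)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(
      x = "complete homoeologous pairs per random draw",
      y = "permutation draws",
      title = sprintf("Observed %d pairs vs null (max %d over %d draws), p = %.2g",
                      object$observed, object$null_max, object$replicates,
                      object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Density plot of log2(AT/AA) homoeolog expression ratios
#' @param object A `ratio_summary` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ratio_summary
#' @export
autoplot.ratio_summary <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = log2_ratio)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "log2(AT FPKM / AA FPKM)", y = "density",
      title = sprintf("%s: %d pairs (mean %.2f, median %.2f); %d excluded",
                      object$group, object$analyzed, object$mean_log2,
                      object$median_log2, object$excluded)
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential expression result
#' @param object A `homeo_de` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot homeo_de
#' @export
autoplot.homeo_de <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = log2fc, y = -log10(pmax(p, 1e-300)),
                                  colour = significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (group 2 / group 1)",
                  y = "-log10 p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Bar chart of the six shared/private-by-panel SNP partition cells
#' @param partition A `panel_partition` result.
#' @return A ggplot.
#' @export
plot_partition <- function(partition) {
  d <- tidy(partition)
  d$cell <- factor(d$cell, levels = d$cell)
  ggplot2::ggplot(d, ggplot2::aes(x = cell, y = n)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = NULL, y = "SNPs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
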