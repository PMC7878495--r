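#' Volcano plot of a DE result
#'
#' @param object A [nb_de_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- object[is.finite(object$log2fc) & !is.na(object$fdr), ]
  df$status <- dplyr::coalesce(df$direction, "not significant")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$fdr), colour = .data$status
  )) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      up_in_indica = "#d73027", up_in_japonica = "#1a9850",
      `not significant` = "grey60"
    )) +
    ggplot2::geom_hline(
      yintercept = -log10(attr(object, "fdr_threshold") %||% 0.05),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "log2 fold change (indica / japonica)",
      y = "-log10 FDR", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of enrichment evidence per cultivar and region class
#'
#' @param object A [run_selection_scan()] result.
#' @param ... Unused.
#' @return A ggplot of -log10 Fisher p by region class, faceted by cultivar.
#' @export
autoplot.enrichment_scan <- function(object, ...) {
  df <- object
  df$region <- factor(df$region,
                      levels = c("five_prime", "coding", "three_prime"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$region, y = -log10(.data$fisher_p)
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~cultivar) +
    ggplot2::labs(x = NULL, y = "-log10 Fisher p") +
    ggplot2::theme_minimal()
}

#' Window-scan significance along each chromosome
#'
#' @param object A [deg_cluster_scan()] result.
#' @param ... Unused.
#' @return A ggplot of -log10 window p by window midpoint.
#' @export
autoplot.window_scan <- function(object, ...) {
  df <- object
  df$mid_mb <- (df$begin + df$end) / 2 / 1e6
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mid_mb, y = -log10(.data$p_value), colour = .data$enriched
  )) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d73027",
                                            `FALSE` = "grey55")) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "window midpoint (Mb)", y = "-log10 p",
                  colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
}

#' Fragment classification bar chart
#'
#' @param object A [classify_fragments()] result.
#' @param ... Unused.
#' @return A ggplot of class percentages.
#' @export
autoplot.fragment_classes <- function(object, ...) {
  df <- dplyr::count(tibble::as_tibble(object), .data$class)
  df$pct <- 100 * df$n / sum(df$n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "% of fragments") +
    ggplot2::theme_minimal()
}

#' Compare pi/Dxy ratios of DEGs and non-DEGs by region class
#'
#' The figure the selection scan summarizes: box plots of the cultivar
#' pi/Dxy ratio for each region class, split by DEG status.
#'
#' @param region_div A [region_diversity()] tibble.
#' @param deg_ids Character vector of DEG gene ids.
#' @param cultivar `"japonica"` or `"indica"`.
#' @return A ggplot.
#' @export
plot_ratio_by_class <- function(region_div, deg_ids,
                                cultivar = c("japonica", "indica")) {
  cultivar <- match.arg(cultivar)
  rcol <- paste0("ratio_", cultivar)
  df <- tibble::as_tibble(region_div)
  df$ratio <- df[[rcol]]
  df <- df[!is.na(df$ratio), ]
  df$status <- ifelse(df$gene_id %in% deg_ids, "DEG", "non-DEG")
  df$region <- factor(df$region,
                      levels = c("five_prime", "coding", "three_prime"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$region, y = .data$ratio, fill = .data$status
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_fill_manual(values = c(DEG = "grey70", `non-DEG` = "grey25")) +
    ggplot2::labs(
      x = NULL, y = sprintf("pi/Dxy (%s vs wild)", cultivar), fill = NULL
    ) +
    ggplot2::theme_minimal()
}
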