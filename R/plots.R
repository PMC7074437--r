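#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PCA scores
#'
#' Scatter of the first two principal components, optionally colored by
#' declared cultivar.
#'
#' @param object A `dus_pca`.
#' @param sheet Optional sample sheet tibble for coloring by cultivar.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.dus_pca <- function(object, sheet = NULL, ...) {
  df <- object$scores
  v <- object$var_explained
  if (!is.null(sheet))
    df <- dplyr::left_join(df, sheet, by = "plant_id")
  aes <- if (is.null(sheet)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$cultivar)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * v[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * v[min(2, length(v))]),
      title = "Genotype PCA") +
    ggplot2::theme_minimal()
}

#' Plot the adjacent-SNP gap distribution
#'
#' Histogram of within-chromosome gaps with the summary threshold marked.
#'
#' @param object A `gap_stats`.
#' @param bins Histogram bins; default 40.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gap_stats <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object$gaps, ggplot2::aes(x = .data$gap)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$threshold_bp,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "gap between adjacent SNPs (bp)", y = "count",
                  title = sprintf("%.1f%% of gaps below %d bp",
                                  100 * object$frac_below,
                                  object$threshold_bp)) +
    ggplot2::theme_minimal()
}

#' Plot per-plant off-type statistics
#'
#' Mean patristic distance to co-cultivar plants per plant, with flagged
#' off-types highlighted.
#'
#' @param object An `offtype_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.offtype_report <- function(object, ...) {
  df <- object$plants[!is.na(object$plants$r), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cultivar, y = .data$r,
                                   colour = .data$flagged)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(y = "mean patristic distance to co-cultivar plants",
                  x = NULL, colour = "off-type",
                  title = "Off-type classification") +
    ggplot2::theme_minimal()
}

#' Plot a kinship matrix heat map
#'
#' @param object A `kinship_matrix`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.kinship_matrix <- function(object, ...) {
  df <- tidy(object)
  # mirror to the full square for display
  df2 <- df[df$plant_a != df$plant_b, ]
  tmp <- df2$plant_a; df2$plant_a <- df2$plant_b; df2$plant_b <- tmp
  full <- dplyr::bind_rows(df, df2)
  ord <- rownames(object)
  full$plant_a <- factor(full$plant_a, levels = ord)
  full$plant_b <- factor(full$plant_b, levels = ord)
  ggplot2::ggplot(full, ggplot2::aes(x = .data$plant_a, y = .data$plant_b,
                                     fill = .data$kinship)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, title = "Genomic kinship") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @importFrom rlang .data
NULL
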