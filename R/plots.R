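#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-SNP attribution fractions
#'
#' Jittered per-site majority-allele fractions by category with the
#' theoretical copy-ratio expectations (1/2 and 3/4) as dashed lines.
#'
#' @param object A `hyb_attribution` tibble from [attribute_reads()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hyb_attribution <- function(object, ...) {
  df <- as_tibble(object)
  theory <- tibble(
    category = c("HOM_HOM_DIFF", "HET_ONE"),
    expected = c(0.5, 0.75)
  ) %>% filter(.data$category %in% df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                   y = .data$majority_fraction)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6,
                         ggplot2::aes(size = .data$n_informative)) +
    ggplot2::geom_segment(
      data = theory,
      ggplot2::aes(x = as.numeric(factor(.data$category,
                                         levels = levels(factor(df$category)))) - 0.3,
                   xend = as.numeric(factor(.data$category,
                                            levels = levels(factor(df$category)))) + 0.3,
                   y = .data$expected, yend = .data$expected),
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "majority-allele read fraction",
                  size = "informative reads",
                  title = "Allelic read fractions at discriminating SNPs") +
    ggplot2::theme_minimal()
}

#' Plot an attribution summary against theoretical expectations
#'
#' Mean ± SD of the majority-allele fraction per category, with the
#' theoretical copy-ratio expectation marked.
#'
#' @param object A `hyb_attribution_summary` from [summarize_attribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hyb_attribution_summary <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(group = paste0(.data$category,
                          ifelse(is.na(.data$het_donor), "",
                                 paste0(" (het ", .data$het_donor, ")"))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean_majority)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_majority - .data$sd_majority,
                   ymax = .data$mean_majority + .data$sd_majority),
      width = 0.15
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$theoretical_majority),
                        shape = 4, size = 4, colour = "firebrick") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "majority-allele fraction (mean ± SD)",
                  title = "Observed vs theoretical allelic ratios",
                  subtitle = "crosses mark the copy-number expectation") +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise expression-profile correlations
#'
#' @param x Expression matrix or data frame (samples in columns; optional
#'   `gene` column ignored).
#' @return A ggplot object tiling the pairwise Pearson correlations.
#' @export
plot_pmcc_heatmap <- function(x) {
  p <- pmcc_pairs(x)
  full <- bind_rows(
    p,
    rename(p, sample_x = "sample_y", sample_y = "sample_x"),
    tibble(sample_x = unique(c(p$sample_x, p$sample_y)),
           sample_y = unique(c(p$sample_x, p$sample_y)), pmcc = 1)
  )
  ggplot2::ggplot(full, ggplot2::aes(.data$sample_x, .data$sample_y,
                                     fill = .data$pmcc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$pmcc)),
                       colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PMCC",
                  title = "Pairwise expression-profile correlation") +
    ggplot2::theme_minimal()
}
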