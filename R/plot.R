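#' @exportS3Method ggplot2::autoplot
autoplot.aagci_screen <- function(object, ...) {
  ggplot2::ggplot(
    object$records,
    ggplot2::aes(
      x = .data$las, y = -log10(pmax(.data$p_adjusted, 1e-300)),
      colour = .data$significant
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(
      yintercept = -log10(object$manifest$fdr), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "liquid-association score",
      y = expression(-log[10] ~ "adjusted p"),
      colour = "LAP"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.aagci_pcc_screen <- function(object, ...) {
  ggplot2::ggplot(
    object$records,
    ggplot2::aes(
      x = .data$correlation, y = -log10(pmax(.data$p_adjusted, 1e-300)),
      colour = .data$significant
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Pearson correlation",
      y = expression(-log[10] ~ "adjusted p"),
      colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.age_directional_sets <- function(object, ...) {
  ggplot2::ggplot(
    object$stats,
    ggplot2::aes(
      x = .data$correlation, y = -log10(pmax(.data$p_adjusted, 1e-300)),
      colour = .data$direction
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "correlation with age",
      y = expression(-log[10] ~ "adjusted p"),
      colour = "direction"
    ) +
    ggplot2::theme_minimal()
}

#' Plot age-stratum correlations of a gene pair
#'
#' Bar panel of the young / middle / old Pearson correlations from
#' [group_correlations()], the standard diagnostic for a liquid-association
#' pair (a monotone trend across strata is the expected signature).
#'
#' @inheritParams group_correlations
#' @return A ggplot object.
#' @export
plot_group_correlations <- function(study, gene_a, gene_b,
                                    cutpoints = c(35, 55)) {
  gc <- group_correlations(study, gene_a, gene_b, cutpoints)
  gc$group <- factor(gc$group, levels = c("young", "middle", "old"))
  ggplot2::ggplot(gc, ggplot2::aes(x = .data$group, y = .data$correlation)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(
      title = sprintf("%s - %s", toupper(gene_a), toupper(gene_b)),
      x = NULL, y = "Pearson correlation (within age stratum)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot top key drivers
#'
#' Lollipop panel of the most significant key-driver candidates from
#' [key_driver_analysis()].
#'
#' @param kd_records Tibble from [key_driver_analysis()].
#' @param top Number of top-ranked genes to show (default 20).
#' @return A ggplot object.
#' @export
plot_key_drivers <- function(kd_records, top = 20) {
  stopifnot(is.data.frame(kd_records))
  shown <- head(arrange(kd_records, .data$rank), top)
  shown$gene <- factor(shown$gene, levels = rev(shown$gene))
  ggplot2::ggplot(
    shown,
    ggplot2::aes(
      x = -log10(pmax(.data$p_adjusted, 1e-300)), y = .data$gene,
      colour = .data$is_kd
    )
  ) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$gene)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$hits)) +
    ggplot2::labs(
      x = expression(-log[10] ~ "adjusted p"), y = NULL,
      colour = "key driver", size = "target hits"
    ) +
    ggplot2::theme_minimal()
}
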