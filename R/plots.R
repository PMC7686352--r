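#' Histogram of tau values by expression tier
#'
#' Mirrors the conventional atlas display: tau distributions split by Top1
#' expression tier (< 1 vs >= 1 TPM), optionally faceted by biotype.
#'
#' @param spec Tibble from [specificity_table()].
#' @param biotypes Optional tibble `gene_id`, `biotype` to facet by.
#' @param binwidth Histogram bin width (default 0.05).
#' @return A ggplot object.
#' @export
plot_tau_distribution <- function(spec, biotypes = NULL, binwidth = 0.05) {
  df <- dplyr::filter(spec, !is.na(.data$tau))
  if (!is.null(biotypes)) {
    df <- dplyr::inner_join(df, biotypes[, c("gene_id", "biotype")],
                            by = "gene_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tau)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "firebrick", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.95, linetype = "dashed") +
    ggplot2::labs(x = expression(tau), y = "genes") +
    ggplot2::theme_minimal()
  if (!is.null(biotypes)) {
    p + ggplot2::facet_grid(
      ggplot2::vars(.data$biotype), ggplot2::vars(.data$expression_tier)
    )
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$expression_tier))
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter of lncRNA versus protein-coding gene density per chromosome
#'
#' @param object A `chrom_density` object from [density_by_chromosome()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chrom_density <- function(object, ...) {
  ggplot2::ggplot(object$per_chrom,
                  ggplot2::aes(x = .data$pcg_per_mb, y = .data$lnc_per_mb,
                               colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "protein-coding genes per Mb", y = "lncRNA genes per Mb",
      colour = "size class",
      subtitle = sprintf("Spearman rho = %.2f, p = %.2g", object$rho,
                         object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Proportion of significantly co-expressed pairs per configuration
#'
#' @param results Correlation results joined to a configuration column.
#' @param config_col Column holding the configuration label.
#' @return A ggplot object.
#' @export
plot_coexpression_by_configuration <- function(results,
                                               config_col = "direction") {
  df <- dplyr::summarise(
    results,
    n = dplyr::n(),
    prop_significant = mean(.data$significant),
    .by = dplyr::all_of(config_col)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[config_col]],
                                   y = .data$prop_significant)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "fraction significantly co-expressed") +
    ggplot2::theme_minimal()
}
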