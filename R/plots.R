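# ggplot2 views of the main result tables.

#' Plot the median binding-fraction curve
#'
#' Step curves of the per-group median fraction of expressed missense/indel
#' mutations called binding, across PHBR cutoffs.
#'
#' @param curve Output of [binding_fraction_curve()].
#' @return A ggplot object.
#' @export
plot_binding_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$cutoff,
                                      y = .data$median_fraction,
                                      colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "PHBR-I cutoff", y = "median binding fraction",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot mutation burden by group
#'
#' Boxplots of the expressed nonsynonymous burden (log10 scale, pseudocount
#' already applied) per escape group, optionally faceted by tumor type.
#'
#' @param burden Burden tibble from [run_pipeline()] (columns `burden`,
#'   `group`, `tumor_type`).
#' @param by_type Facet by tumor type?
#' @return A ggplot object.
#' @export
plot_burden <- function(burden, by_type = FALSE) {
  p <- ggplot2::ggplot(burden, ggplot2::aes(x = .data$group,
                                            y = .data$burden,
                                            fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "expressed nonsynonymous mutations + 1") +
    ggplot2::theme_minimal()
  if (by_type) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(merge_crc(.data$tumor_type)))
  }
  p
}

#' Plot escape-mutation VAF percentile distributions
#'
#' Overlaid densities of the within-tumor allelic-fraction percentiles of
#' B2M versus HLA escape mutations, with the early/late stratum cutoffs.
#'
#' @param timing Output of [escape_timing()].
#' @param low,high Stratum cutoffs drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_vaf_percentiles <- function(timing, low = 40, high = 60) {
  df <- timing %>%
    mutate(kind = ifelse(.data$gene == "B2M", "B2M", "HLA")) %>%
    filter(.data$group %in% c("B2M_MUT", "HLA_MUT"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percentile,
                                   colour = .data$kind)) +
    ggplot2::geom_density(bw = 8) +
    ggplot2::geom_vline(xintercept = c(low, high), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "within-tumor VAF percentile", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_binding_curve
#' @param object,... Autoplot interface: a `"neo_pipeline"` object.
#' @export
autoplot.neo_pipeline <- function(object, ...) {
  plot_binding_curve(object$binding_curve)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
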