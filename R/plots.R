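#' Plot a hotspot scan along the genome
#'
#' Bars show the per-bin -log10 Fisher p-value faceted by chromosome; points
#' mark the density fold ratio of called hotspots (secondary-axis free: fold
#' is annotated, not rescaled).
#'
#' @param object A `varscape_hotspots` tibble from [call_hotspots()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot varscape_hotspots
#' @export
autoplot.varscape_hotspots <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(mid = (.data$start + .data$end) / 2e6,
           neg_log10_p = -log10(pmax(.data$p, .Machine$double.xmin)))
  th <- attr(object, "thresholds")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$neg_log10_p)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$is_hotspot), width = 0.9) +
    ggplot2::geom_point(data = df[df$is_hotspot, , drop = FALSE],
                        ggplot2::aes(y = .data$neg_log10_p + 0.5),
                        colour = "red", size = 1) +
    ggplot2::geom_hline(yintercept = -log10(unname(th["p_max"])),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_grid(. ~ .data$chrom, scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  title = "Variant-density hotspots (cohort vs reference)")
}

#' Plot an enrichment report
#'
#' Dot plot of -log10 p by feature set and variant class, point size mapping
#' the density fold ratio.
#'
#' @param object A `varscape_enrichment` tibble (single test or report).
#' @param alpha Significance line to draw (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot varscape_enrichment
#' @export
autoplot.varscape_enrichment <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object) %>%
    filter(!is.na(.data$p)) %>%
    mutate(neg_log10_p = -log10(pmax(.data$p, .Machine$double.xmin)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$neg_log10_p,
                                   colour = .data$class,
                                   size = .data$fold)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Feature-set enrichment",
                  size = "fold", colour = "variant class") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot per-sample QC metrics
#'
#' @param report Output of [qc_report()] (the cohort summary row is dropped).
#' @return A ggplot object showing Het/Hom and Ti/Tv per sample.
#' @export
plot_qc <- function(report) {
  df <- report %>%
    filter(.data$sample != "<cohort>") %>%
    select("sample", "het_hom", "titv") %>%
    tidyr::pivot_longer(c("het_hom", "titv"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-sample QC") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
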