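#' Plot a metaplot profile
#'
#' Mean line with a +/- 1 SE ribbon; vertical guides mark the body
#' boundaries.
#'
#' @param object A `meta_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_profile <- function(object, ...) {
  n_fl <- attr(object, "n_flank_bins") %||% 0
  n_body <- attr(object, "n_body_bins")
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "scaled position (5' → 3')", y = "signal") +
    ggplot2::theme_classic()
  if (n_fl > 0) {
    p <- p + ggplot2::geom_vline(xintercept = c(n_fl + 0.5,
                                                n_fl + n_body + 0.5),
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot heritable-DMR percentages across the intersection chain
#'
#' @param object A `heritability_report`.
#' @param which `"pct_reference"` (primary) or `"pct_target"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.heritability_report <- function(object,
                                         which = c("pct_reference",
                                                   "pct_target"), ...) {
  which <- match.arg(which)
  df <- as_tibble(object) |>
    mutate(target = factor(.data$target, levels = .data$target))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data[[which]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "% heritable hyper DMRs") +
    ggplot2::theme_classic()
}

#' Plot per-cytosine methylation over a region (amplicon-style bars)
#'
#' @param object A `region_methylation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_methylation <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$pos, y = .data$level)) +
    ggplot2::geom_col(width = 2, fill = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = sprintf("%s position", object$chrom),
                  y = "methylation level") +
    ggplot2::theme_classic()
}

#' Chromosome-scale windowed methylation-difference curves
#'
#' @param diff_windows Output of [windowed_genome_difference()].
#' @return A ggplot faceted by chromosome.
#' @export
plot_windowed_difference <- function(diff_windows) {
  ggplot2::ggplot(diff_windows,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$mean_difference)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(na.rm = TRUE, colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "methylation difference") +
    ggplot2::theme_classic()
}

#' Hyper/hypo DMR counts per cluster
#'
#' @param partitioned Output of [partition_by_cluster()].
#' @return A ggplot.
#' @export
plot_cluster_dmr_counts <- function(partitioned) {
  df <- partitioned |>
    count(cluster = factor(.data$cluster, exclude = NULL), .data$direction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(hyper = "firebrick",
                                          hypo = "steelblue")) +
    ggplot2::labs(x = "cluster", y = "DMR bins") +
    ggplot2::theme_classic()
}
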