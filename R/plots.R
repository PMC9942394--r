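#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style tracks of window statistics
#'
#' F_ST and the log2 diversity ratio along the genome, faceted by
#' statistic, with optional threshold lines. Masked windows and infinite
#' ratios are dropped from the panel.
#'
#' @param object A `sweep_windows` tibble from [window_stats()].
#' @param thresholds Optional [outlier_thresholds()] drawn as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_windows
#' @export
autoplot.sweep_windows <- function(object, thresholds = NULL, ...) {
  df <- tidyr::pivot_longer(
    dplyr::filter(tibble::as_tibble(object), !.data$masked),
    cols = c("fst", "log2_pi_ratio"),
    names_to = "statistic", values_to = "value")
  df <- dplyr::filter(df, is.finite(.data$value))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(statistic ~ chrom, scales = "free",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    hl <- data.frame(statistic = c("fst", "log2_pi_ratio"),
                     value = c(thresholds$fst_threshold,
                               thresholds$pi_ratio_threshold))
    p <- p + ggplot2::geom_hline(data = hl,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Composite-likelihood score track
#'
#' @param object An `xpclr_scores` tibble from [xpclr_scores()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot xpclr_scores
#' @export
autoplot.xpclr_scores <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grid_pos / 1e6,
                                   y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "XP-CLR score") +
    ggplot2::theme_minimal()
}

#' Allele-frequency trajectories along the altitude gradient
#'
#' One line per candidate site across populations ordered by altitude;
#' flagged altitude-increasing sites are highlighted.
#'
#' @param trajectory Output of [allele_frequency_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectory) {
  pops <- setdiff(names(trajectory),
                  c("chrom", "pos", "rank_correlation", "total_rise",
                    "incomplete", "altitude_increasing"))
  df <- tidyr::pivot_longer(trajectory, cols = dplyr::all_of(pops),
                            names_to = "population", values_to = "freq")
  df$population <- factor(df$population, levels = pops)
  df$site <- paste0(df$chrom, ":", df$pos)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population, y = .data$freq,
                                   group = .data$site,
                                   colour = .data$altitude_increasing)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "population (by altitude)",
                  y = "alt-allele frequency", colour = "increasing") +
    ggplot2::theme_minimal()
}
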