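#' Rank-ordered Function Potential plot
#'
#' FP score against rank (log scale), hotspots with known function
#' highlighted, with the grouping median as a reference line.
#'
#' @param object an `fp_ranking` from [rank_hotspots()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fp_ranking
#' @export
autoplot.fp_ranking <- function(object, ...) {
  df <- tidy.fp_ranking(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$fp)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$family_median_fp),
                        color = "red", linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(color = .data$known_function),
                        size = 1.6) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "#1b7837", `FALSE` = "grey55"),
      labels = c(`TRUE` = "known function", `FALSE` = "unknown"),
      name = NULL) +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::facet_wrap(~family_id, scales = "free") +
    ggplot2::labs(x = "hotspot rank", y = "Function Potential (FP)") +
    ggplot2::theme_minimal()
}

#' Known-fraction threshold curve plot
#'
#' @param curve tibble from [known_fraction_vs_threshold()].
#' @return a ggplot object.
#' @export
plot_threshold_curve <- function(curve) {
  ggplot2::ggplot(curve[!is.na(curve$pct_known), ],
                  ggplot2::aes(x = .data$threshold,
                               y = 100 * .data$pct_known)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "FP threshold (multiples of median)",
                  y = "% hotspots with known function") +
    ggplot2::theme_minimal()
}

#' PTM load histogram
#'
#' @param load tibble from [ptm_load()].
#' @param bins histogram bin count.
#' @return a ggplot object.
#' @export
plot_ptm_load <- function(load, bins = 20) {
  ggplot2::ggplot(load, ggplot2::aes(x = .data$load)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(x = "PTM load (PTMs per residue)", y = "proteins") +
    ggplot2::theme_minimal()
}
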