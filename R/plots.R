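# Figure helpers mirroring the standard presentation of break-apart FISH
# screens: distance jitter plots, event-frequency crossbars with CIs, and
# per-channel spot-count histograms.

#' Jitter plot of per-Red minimum Red/Green distances
#'
#' @param alleles Allele-distance table (`call_events()$alleles`), optionally
#'   with a `condition` column for faceting along the x axis.
#' @param thresholds A [ba_thresholds()] drawn as a dashed reference line.
#' @return A ggplot object.
#' @export
plot_distance_jitter <- function(alleles, thresholds = ba_thresholds()) {
  if (!"condition" %in% names(alleles)) alleles$condition <- "all"
  ggplot2::ggplot(alleles,
                  ggplot2::aes(x = .data$condition, y = .data$rg_min)) +
    ggplot2::geom_jitter(width = 0.3, size = 0.4, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = thresholds$proximity_px,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = "min Red/Green distance (px)") +
    ggplot2::theme_classic()
}

#' Crossbar plot of event-positive frequencies with confidence intervals
#'
#' @param summaries Condition summary table ([summarize_condition()] rows).
#' @return A ggplot object.
#' @export
plot_event_frequency <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$condition,
                               y = 100 * .data$proportion)) +
    ggplot2::geom_crossbar(ggplot2::aes(ymin = 100 * .data$ci_low,
                                        ymax = 100 * .data$ci_high),
                           width = 0.5) +
    ggplot2::facet_wrap(~event_class, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "event-positive cells (%)") +
    ggplot2::theme_classic()
}

#' Histogram of FISH signal counts per nucleus
#'
#' @param hist_df Output of [spot_count_histogram()] (optionally with
#'   `channel` and `condition` columns bound on for faceting).
#' @return A ggplot object.
#' @export
plot_spot_count_histogram <- function(hist_df) {
  g <- ggplot2::ggplot(hist_df,
                       ggplot2::aes(x = .data$n_spots,
                                    y = 100 * .data$frequency)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "FISH signals per nucleus", y = "nuclei (%)") +
    ggplot2::theme_classic()
  if (all(c("channel", "condition") %in% names(hist_df))) {
    g <- g + ggplot2::facet_grid(condition ~ channel)
  } else if ("channel" %in% names(hist_df)) {
    g <- g + ggplot2::facet_wrap(~channel)
  }
  g
}
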