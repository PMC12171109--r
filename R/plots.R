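#' Swarm/box plot of a per-cell metric by condition
#'
#' Boxplots with jittered single-cell points, the display convention used
#' for the granularity statistics. `log10 = TRUE` puts the y axis on a log10
#' scale (display only; tests always run on raw values). Skewness can be
#' negative, so it is plotted on a linear axis by default.
#'
#' @param metrics per-cell metrics table from [cell_metrics()].
#' @param metric column to plot.
#' @param log10 use a log10 y axis.
#' @return a ggplot object.
#' @export
plot_metric_by_condition <- function(metrics, metric = "frac_area_occupied",
                                     log10 = TRUE) {
  stopifnot(metric %in% names(metrics))
  p <- ggplot2::ggplot(metrics, ggplot2::aes(
    x = .data$condition, y = .data[[metric]], colour = .data$condition)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.6, size = 1) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none")
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}

#' Decay curve of one transcript with both window fits
#'
#' Log10 normalized counts against treatment time, with the early- and
#' late-window regression lines overlaid and the fitted half-lives in the
#' subtitle.
#'
#' @param table reference-normalized count table (with `norm_count`).
#' @param fits result row(s) of [two_phase_halflives()].
#' @param transcript transcript to plot.
#' @param condition condition to plot (default: first present).
#' @return a ggplot object.
#' @export
plot_decay_fit <- function(table, fits, transcript,
                           condition = table$condition[1]) {
  sub <- table[table$transcript == transcript &
                 table$condition == condition, ]
  if (nrow(sub) == 0) stop("no rows for ", transcript)
  fr <- fits[fits$transcript == transcript & fits$condition == condition, ]
  means <- stats::aggregate(norm_count ~ timepoint_h, sub, mean)
  w <- attr(fits, "windows") %||%
    list(early = c(0, 2, 5), late = c(5, 8, 24))
  line_df <- function(window, slope) {
    anchor <- window[1]
    y0 <- means$norm_count[means$timepoint_h == anchor]
    t <- seq(min(window), max(window), length.out = 20)
    data.frame(timepoint_h = t,
               norm_count = y0 * 10^(slope * (t - anchor)),
               window = if (anchor == w$early[1]) "early" else "late")
  }
  lines <- rbind(line_df(w$early, fr$early_slope),
                 line_df(w$late, fr$late_slope))
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$timepoint_h,
                                    y = .data$norm_count)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_point(data = means, size = 3, colour = "darkcyan") +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(group = .data$window,
                                    colour = .data$window)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "normalized counts (log10)",
                  title = paste(transcript, condition),
                  subtitle = sprintf("t1/2 early %.2f h, late %.2f h (%s)",
                                     fr$t_early_half, fr$t_late_half,
                                     fr$classification)) +
    ggplot2::theme_classic()
}

#' Metagene ribbon plot of the labeled RNA fraction during recovery
#'
#' Mean relative labeled counts with the confidence ribbon and per-replicate
#' points.
#'
#' @param metagene result of [transient_metagene()].
#' @return a ggplot object.
#' @export
plot_metagene <- function(metagene) {
  s <- metagene$series
  ggplot2::ggplot(s, ggplot2::aes(x = .data$timepoint_h, y = .data$mean_rel)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_rel - .data$ci_halfwidth,
                                      ymax = .data$mean_rel + .data$ci_halfwidth),
                         fill = "turquoise", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = metagene$replicate_means,
                        ggplot2::aes(y = .data$rel), alpha = 0.5) +
    ggplot2::labs(x = "recovery time (h)",
                  y = "labeled counts relative to reference") +
    ggplot2::theme_classic()
}
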