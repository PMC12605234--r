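#' Plot a PPG recording with optional fiducials
#'
#' @param object A `ppg_recording` tibble.
#' @param beats Optional `ppg_beats` tibble; systolic peaks, valleys, notch
#'   and reflected peaks are overlaid.
#' @param window_s Optional two-element time window (s) to restrict the view.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppg_recording <- function(object, beats = NULL, window_s = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(window_s)) {
    df <- df[df$t_s >= window_s[1] & df$t_s <= window_s[2], ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$ppg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "PPG amplitude (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(beats)) {
    x <- object$ppg
    fid <- bind_rows(
      tibble(t = beats$peak_s, y = x[beats$peak_idx], what = "systolic peak"),
      tibble(t = beats$onset_s, y = x[beats$onset_idx], what = "valley"),
      tibble(t = beats$notch_s[!beats$p2_missing],
             y = x[beats$notch_idx[!beats$p2_missing]], what = "dicrotic notch"),
      tibble(t = beats$p2_s[!beats$p2_missing],
             y = x[beats$p2_idx[!beats$p2_missing]], what = "reflected peak")
    )
    if (!is.null(window_s)) {
      fid <- fid[fid$t >= window_s[1] & fid$t <= window_s[2], ]
    }
    p <- p + ggplot2::geom_point(
      data = fid, ggplot2::aes(x = .data$t, y = .data$y, colour = .data$what),
      size = 1.6
    ) + ggplot2::labs(colour = NULL)
  }
  p
}

#' Plot a cohort comparison report
#'
#' Effect sizes per feature, coloured by classification, with the
#' conventional small/medium/large thresholds marked.
#'
#' @param object A `ppg_report` from [compare_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppg_report <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$eps2), ]
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eps2, y = .data$feature,
                                   fill = .data$effect_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(0.01, 0.06, 0.14), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = expression(epsilon^2), y = NULL, fill = "effect") +
    ggplot2::theme_minimal()
}
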