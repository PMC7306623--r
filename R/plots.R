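#' Plot group-mean decoding accuracy over time
#'
#' Mean real-label accuracy per analysis window with standard-error ribbons
#' per group; the dashed line marks the theoretical chance level and the
#' dotted grey curve the grand-mean shuffled-label null.
#'
#' @param curves Decoding curves with a `group` column.
#' @param chance Chance level (0.5 for two balanced classes).
#' @return A ggplot object.
#' @export
plot_decoding <- function(curves, chance = 0.5) {
  summ <- curves |>
    dplyr::group_by(group, t_start) |>
    dplyr::summarise(
      mean_real = mean(acc_real),
      se_real = sd(acc_real) / sqrt(dplyr::n()),
      mean_shuffled = mean(acc_shuffled),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = t_start, y = mean_real,
                                     colour = group, fill = group)) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = mean_shuffled), colour = "grey60",
                       linetype = "dotted") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean_real - se_real,
                                      ymax = mean_real + se_real),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time relative to response (ms)",
                  y = "classification accuracy",
                  title = "Sliding-window decoding of response type") +
    ggplot2::theme_minimal()
}

# 10 Hz low-pass (moving-average approximation) used for display only,
# never in measurement.
display_smooth <- function(v, srate, cutoff_hz = 10) {
  k <- max(1, round(srate / cutoff_hz / 2))
  stats::filter(v, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
}

#' Plot condition-average waveforms at one electrode
#'
#' @param erps Named list of `erp` objects (names become condition labels).
#' @param electrode Channel label to plot.
#' @param smooth Apply the 10 Hz display filter (illustration only).
#' @return A ggplot object.
#' @export
plot_erp <- function(erps, electrode, smooth = TRUE) {
  df <- purrr::imap_dfr(erps, function(e, nm) {
    v <- e$wave[electrode, ]
    if (smooth) v <- as.numeric(display_smooth(v, e$srate))
    tibble(condition = nm, time = e$times, amplitude = v, units = e$units)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = amplitude,
                                   colour = condition)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (ms)", y = df$units[1], title = electrode) +
    ggplot2::theme_minimal()
}
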