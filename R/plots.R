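#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evaluation report
#'
#' Classification error per fold, one box per classifier, faceted by
#' analysis protocol.
#'
#' @param object An `emg_eval` tibble (see [evaluate_protocols()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emg_eval
#' @export
autoplot.emg_eval <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$classifier, y = .data$ce, fill = .data$classifier
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$analysis)) +
    ggplot2::labs(x = NULL, y = "classification error") +
    ggplot2::theme_minimal()
}

#' Plot a drift sweep
#'
#' Mean pairwise-day classification error versus the day-shift SD, one line
#' per seed.
#'
#' @param object An `emg_drift_sweep` (see [drift_sweep()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emg_drift_sweep
#' @export
autoplot.emg_drift_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$shift_sd, y = .data$mean_pair_ce,
    group = factor(.data$seed), colour = factor(.data$seed)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day shift SD (channel units)",
                  y = "mean pairwise-day CE", colour = "seed") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairs-of-days triangle table
#'
#' @param M Day x day matrix from [pair_triangle_table()].
#' @return A ggplot tile map (diagonal cells blank).
#' @export
plot_pair_matrix <- function(M) {
  df <- tidyr::expand_grid(
    train_day = rownames(M), test_day = colnames(M)
  )
  df$ce <- as.vector(t(M))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$test_day, y = .data$train_day, fill = .data$ce
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(rownames(M))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "CE") +
    ggplot2::theme_minimal()
}

#' Plot a few seconds of a recording
#'
#' Stacked channel traces with annotated contraction segments shaded.
#'
#' @param object An `emg_recording`.
#' @param t_max Seconds to show from the start.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emg_recording
#' @export
autoplot.emg_recording <- function(object, t_max = 20, ...) {
  n <- min(nrow(object$samples), round(t_max * object$fs))
  df <- tibble::tibble(
    t = rep((seq_len(n) - 1) / object$fs, object$channels),
    channel = rep(factor(seq_len(object$channels)), each = n),
    value = as.vector(object$samples[seq_len(n), ])
  )
  ann <- object$annotations
  ann <- ann[ann$start_sample < n, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value))
  if (nrow(ann) > 0) {
    shade <- tibble::tibble(
      xmin = ann$start_sample / object$fs,
      xmax = pmin(ann$end_sample, n) / object$fs,
      movement = ann$movement
    )
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$movement),
      alpha = 0.15, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "EMG (a.u.)") +
    ggplot2::theme_minimal()
}
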