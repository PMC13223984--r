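#' Plot a pooled periodogram
#'
#' Power spectrum with the analysis frequency and its harmonic marked.
#'
#' @param periodogram Tibble from [pooled_periodogram()].
#' @param analysis_freq Frequency to highlight, Hz.
#' @return A ggplot object.
#' @export
plot_periodogram <- function(periodogram, analysis_freq = 20) {
  ggplot2::ggplot(periodogram, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(analysis_freq, 2 * analysis_freq),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(Power~(mu*V^2)),
                  title = "Pooled mean periodogram") +
    ggplot2::theme_minimal()
}

#' Plot a noise-adjusted amplitude topography
#'
#' Schematic scalp view of the per-electrode noise-adjusted amplitude for
#' one sweep step.
#'
#' @param topo Tibble from [topography_array()].
#' @return A ggplot object.
#' @export
plot_topography <- function(topo) {
  circ <- tibble::tibble(theta = seq(0, 2 * pi, length.out = 181))
  ggplot2::ggplot(topo, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = data.frame(x = sin(circ$theta),
                                         y = cos(circ$theta)),
                       colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$adj_amp), size = 5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$electrode), size = 2,
                       vjust = 2.2) +
    ggplot2::scale_colour_viridis_c(name = expression(adj.~amp~(mu*V))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Noise-adjusted amplitude topography") +
    ggplot2::theme_void()
}

#' Plot the z-score profile of a sweep with its extracted threshold
#'
#' @param table Spectral table rows for one electrode, one
#'   (condition, direction).
#' @param result Optional `threshold_result` row; the threshold step is
#'   marked.
#' @param z_criterion Criterion line (default 2.33).
#' @return A ggplot object.
#' @export
plot_z_profile <- function(table, result = NULL, z_criterion = 2.33) {
  p <- ggplot2::ggplot(table,
                       ggplot2::aes(x = .data$step_index, y = .data$z)) +
    ggplot2::geom_hline(yintercept = z_criterion, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Sweep step", y = "z-scored amplitude") +
    ggplot2::theme_minimal()
  if (!is.null(result) && isTRUE(result$valid) && !is.na(result$step_index)) {
    p <- p + ggplot2::geom_point(
      data = table[table$step_index == result$step_index, ],
      colour = "red", size = 3
    ) +
      ggplot2::labs(subtitle = sprintf("threshold: %.3g (%s method)",
                                       result$threshold_value, result$method))
  }
  p
}

#' Autoplot method for QUEST states
#'
#' Posterior over candidate thresholds, with the tested levels as a rug.
#'
#' @param object A `quest_state`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quest_state
#' @export
autoplot.quest_state <- function(object, ...) {
  post <- tidy.quest_state(object)
  p <- ggplot2::ggplot(post,
                       ggplot2::aes(x = .data$threshold, y = .data$posterior)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Candidate threshold", y = "Posterior probability",
                  title = "QUEST posterior") +
    ggplot2::theme_minimal()
  if (nrow(object$history) > 0) {
    p <- p + ggplot2::geom_rug(data = object$history,
                               ggplot2::aes(x = .data$level),
                               inherit.aes = FALSE, alpha = 0.5)
  }
  p
}
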