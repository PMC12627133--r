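#' Plot a stimulus set and its optimal bound
#'
#' Scatter of a stimulus set in normalized coordinates, colored by true
#' category, optionally with a decision bound overlaid.
#'
#' @param stimuli A stimulus tibble.
#' @param bound Optional [linear_bound()] to draw.
#' @return A ggplot object.
#' @export
plot_stimulus_space <- function(stimuli, bound = NULL) {
  p <- ggplot2::ggplot(stimuli,
                       ggplot2::aes(.data$x_norm, .data$y_norm,
                                    colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "dimension x (normalized)",
                  y = "dimension y (normalized)", colour = "category") +
    ggplot2::theme_minimal()
  if (!is.null(bound)) {
    if (bound$b == 0) {
      p <- p + ggplot2::geom_vline(xintercept = -bound$c / bound$a,
                                   linetype = 2)
    } else {
      p <- p + ggplot2::geom_abline(slope = -bound$a / bound$b,
                                    intercept = -bound$c / bound$b,
                                    linetype = 2)
    }
  }
  p
}

#' Plot blockwise learning curves
#'
#' Group mean accuracy across training blocks and the generalization test,
#' with SEM error bars, faceted by modality and category type; the dashed
#' line marks chance.
#'
#' @param summary Output of [blockwise_accuracy()].
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(summary) {
  summary <- dplyr::mutate(summary,
    block = factor(.data$block, levels = c(as.character(1:8), "test")))
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$block, .data$mean_accuracy,
                               colour = .data$group, group = .data$group)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sem,
      ymax = .data$mean_accuracy + .data$sem), size = 0.3) +
    ggplot2::facet_grid(modality ~ task) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "block", y = "mean accuracy", colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot strategy proportions across blocks
#'
#' Stacked proportions of strategy labels per block, faceted by group and
#' task within one modality at a time (facet over all four conditions).
#'
#' @param proportions Output of [strategy_proportions()].
#' @return A ggplot object.
#' @export
plot_strategy_proportions <- function(proportions) {
  proportions <- dplyr::mutate(proportions,
    block = factor(.data$block, levels = c(as.character(1:8), "test")),
    label = factor(.data$label,
                   levels = c("procedural", "uni_x", "uni_y", "random")))
  ggplot2::ggplot(proportions,
                  ggplot2::aes(.data$block, .data$proportion,
                               fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(group ~ modality + task) +
    ggplot2::labs(x = "block", y = "proportion of participants",
                  fill = "strategy") +
    ggplot2::theme_minimal()
}

#' Plot generalization-transfer scores
#'
#' @param transfer Output of [transfer_scores()].
#' @return A ggplot object.
#' @export
plot_transfer <- function(transfer) {
  ggplot2::ggplot(transfer,
                  ggplot2::aes(interaction(.data$modality, .data$task),
                               .data$transfer, fill = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "task", y = "transfer (test - final block accuracy)",
                  fill = "group") +
    ggplot2::theme_minimal()
}
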