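#' Plot a cell set
#'
#' Scatter plot of cell centers colored by class label, in image
#' orientation (y grows downward).
#'
#' @param cells A cell-set tibble.
#' @param point_size Point size passed to [ggplot2::geom_point()].
#' @return A ggplot object.
#' @export
plot_cells <- function(cells, point_size = 0.8) {
  cells <- as_cell_set(cells, allow_diverse = TRUE)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$center_x, y = .data$center_y,
                                      colour = .data$label)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [px]", y = "y [px]", colour = "class") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ap_result <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("%s: AP = %.3f", object$class_label, object$ap),
      x = "recall", y = "precision"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise agreement report
#'
#' Dot plot of kappa per rater pair and variant, the at-a-glance view of
#' which disagreements stem from missed cells (Regular Category low) versus
#' label confusion (Listwise Deletion / Gwet low).
#'
#' @param report Tibble from [pairwise_agreement_report()].
#' @return A ggplot object.
#' @export
plot_agreement <- function(report) {
  report <- dplyr::mutate(
    report, pair = paste(.data$left_source, .data$right_source, sep = " vs ")
  )
  ggplot2::ggplot(report, ggplot2::aes(x = .data$pair, y = .data$kappa,
                                       colour = .data$variant)) +
    ggplot2::geom_point(size = 2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = c(0.6, 0.8), linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "kappa") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
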