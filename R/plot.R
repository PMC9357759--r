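#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training history
#'
#' Loss and accuracy curves over epochs for a fitted model.
#'
#' @param object an `msstgcn_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.msstgcn_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$train_loss,
                   metric = "train loss"),
    tibble::tibble(epoch = h$epoch, value = h$train_accuracy,
                   metric = "train accuracy"),
    tibble::tibble(epoch = h$epoch, value = h$val_accuracy,
                   metric = "validation accuracy")
  )
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "MS-ST-GCN training history") +
    ggplot2::theme_minimal()
}

#' Plot an alpha-sweep table
#'
#' Top-1 accuracy as a function of the score-fusion weight, with the best
#' alpha marked.
#'
#' @param sweep tibble from [run_alpha_sweep()].
#' @return a ggplot object.
#' @export
plot_alpha_sweep <- function(sweep) {
  best <- attr(sweep, "best_alpha")
  p <- ggplot2::ggplot(sweep,
                       ggplot2::aes(.data$alpha, .data$top1_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "top-1 accuracy (%)",
                  title = "Two-stream score fusion sweep") +
    ggplot2::theme_minimal()
  if (!is.null(best)) {
    p <- p + ggplot2::geom_vline(xintercept = best, linetype = "dashed")
  }
  p
}

#' Plot a skeleton layout
#'
#' The template pose with bone edges, a quick sanity view of a layout file.
#'
#' @param layout a `skeleton_layout`.
#' @return a ggplot object.
#' @export
plot_layout <- function(layout) {
  stopifnot(inherits(layout, "skeleton_layout"))
  joints <- tibble::tibble(
    x = layout$template_pose[, 1L], y = layout$template_pose[, 2L],
    name = layout$joint_names
  )
  bones <- tibble::tibble(
    x = layout$template_pose[layout$edges[, 1L], 1L],
    y = layout$template_pose[layout$edges[, 1L], 2L],
    xend = layout$template_pose[layout$edges[, 2L], 1L],
    yend = layout$template_pose[layout$edges[, 2L], 2L]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = bones,
      ggplot2::aes(.data$x, .data$y, xend = .data$xend, yend = .data$yend),
      color = "grey50") +
    ggplot2::geom_point(data = joints, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = layout$name, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
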