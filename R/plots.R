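#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trajectory plot of estimated marginal means
#'
#' Mean and standard error per group across the relative timeline, the
#' standard presentation for diagnosis-anchored biomarker trajectories.
#'
#' @param object A `trajectory_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_fit <- function(object, ...) {
  emm <- estimate_marginal_means(object)
  ggplot2::ggplot(
    emm,
    ggplot2::aes(
      x = .data$relative_label, y = .data$emmean,
      colour = .data$group, group = .data$group
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$emmean - .data$se,
        ymax = .data$emmean + .data$se
      ),
      width = 0.1
    ) +
    ggplot2::labs(
      x = "Time relative to classification",
      y = object$outcome,
      colour = "Group",
      title = sprintf(
        "Estimated marginal means (%s, %s)",
        object$outcome, object$adjustment
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.trajectory_fit
#' @param fit A `trajectory_fit`.
#' @export
plot_trajectory <- function(fit, ...) autoplot(fit, ...)
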