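# ggplot2 displays: forest plot of the three model iterations and the
# misspecification sweep panels.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of hazard ratios across model iterations
#'
#' Hazard ratio (log scale) with 95% CI per ethnic group, one colour per
#' model iteration, reference line at HR = 1.
#'
#' @param object A `model_iterations` object (or the tibble returned by
#'   [summarise_hr()], via [plot_forest()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot model_iterations
#' @export
autoplot.model_iterations <- function(object, ...) {
  plot_forest(summarise_hr(object))
}

#' @rdname autoplot.model_iterations
#' @param hr Tibble from [summarise_hr()].
#' @export
plot_forest <- function(hr) {
  hr <- dplyr::mutate(
    hr,
    iteration = factor(.data$iteration, levels = unique(.data$iteration))
  )
  ggplot2::ggplot(
    hr,
    ggplot2::aes(
      x = .data$hazard_ratio, y = .data$ethnicity,
      xmin = .data$ci_lower, xmax = .data$ci_upper,
      colour = .data$iteration, shape = .data$iteration
    )
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Hazard ratio for death (vs White, log scale)", y = NULL,
      colour = "Model", shape = "Model"
    ) +
    ggplot2::theme_minimal()
}

#' Panels of the misspecification sweep
#'
#' One panel per shifted coefficient: weighted hazard ratios (with 95% CI)
#' by misspecification level and ethnic group, with the unshifted weighted
#' estimates as horizontal reference lines. Skipped scenarios appear as
#' gaps.
#'
#' @param object A `sensitivity_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sensitivity_result
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  res <- dplyr::filter(object$results, !is.na(.data$hazard_ratio))
  ggplot2::ggplot(
    res,
    ggplot2::aes(
      x = factor(.data$level), y = .data$hazard_ratio,
      ymin = .data$ci_lower, ymax = .data$ci_upper,
      colour = .data$ethnicity, group = .data$ethnicity
    )
  ) +
    ggplot2::geom_hline(
      data = object$base_hr,
      ggplot2::aes(yintercept = .data$hazard_ratio, colour = .data$ethnicity),
      linetype = "dotted", alpha = 0.7
    ) +
    ggplot2::geom_pointrange(
      position = ggplot2::position_dodge(width = 0.5), size = 0.3
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(
      x = "Misspecification level (%)",
      y = "Weighted hazard ratio for death (vs White, log scale)",
      colour = "Ethnic group"
    ) +
    ggplot2::theme_minimal()
}
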