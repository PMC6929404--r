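#' Forest plot of a pooled fit
#'
#' Per-study odds ratios with 95% intervals (point size proportional to
#' pooling weight) above the pooled estimate and its interval, on a log
#' axis.
#'
#' @param object A `meta_pool` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_pool <- function(object, ...) {
  d <- tidy(object)
  d$label <- make.unique(paste0(d$label, ""))
  d$label <- factor(d$label, levels = rev(d$label))
  pooled <- tibble(
    label = "Pooled", or = object$or,
    ci_low = object$ci_low, ci_high = object$ci_high, weight = NA_real_
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$or, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), shape = 15,
                        show.legend = FALSE) +
    ggplot2::geom_point(data = pooled, shape = 18, size = 4) +
    ggplot2::geom_errorbarh(
      data = pooled,
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.3
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL)
}

#' Funnel plot
#'
#' Study log odds ratios against their standard errors (largest at the
#' bottom) with the pseudo 95% confidence funnel around the pooled
#' estimate.
#'
#' @param data A funnel coordinate table from [funnel_data()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(data) {
  d <- dplyr::arrange(data, .data$se)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ln_or, y = .data$se)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$center),
                        linetype = "dashed") +
    ggplot2::geom_path(ggplot2::aes(x = .data$funnel_low), linetype = "dotted") +
    ggplot2::geom_path(ggplot2::aes(x = .data$funnel_high), linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "log odds ratio", y = "standard error")
}
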