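#' Plot per-structure presence proportions
#'
#' Dot plot of the proportion of mice with tracer presence in each
#' structure, faceted by tracer, coloured by group — the graphical
#' counterpart of the presence table.
#'
#' @param proportions Output of [tabulate_proportions()].
#' @return A ggplot object.
#' @export
plot_presence_proportions <- function(proportions) {
  proportions$structure <- factor(proportions$structure,
                                  levels = rev(scored_structures()))
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = .data$proportion, y = .data$structure,
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2.5, position = ggplot2::position_dodge(0.5)) +
    ggplot2::facet_wrap(~tracer) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "proportion of mice with tracer presence",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot dispersion volumes by group and tracer
#'
#' @param volumes Tibble with `volume_mm3`, `group`, `tracer` (e.g. the
#'   `volumes` element of [run_experiment()]).
#' @return A ggplot object.
#' @export
plot_dispersion_volumes <- function(volumes) {
  ggplot2::ggplot(volumes,
                  ggplot2::aes(x = .data$group, y = .data$volume_mm3,
                               colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.08, size = 2.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          linewidth = 0.3, colour = "grey30") +
    ggplot2::facet_wrap(~tracer, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "dispersion volume (mm³)") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest-style plot of a fitted presence GEE
#'
#' @param object A `cryoclear_gee`.
#' @param ... Unused.
#' @return A ggplot object showing the OR and its 95 percent CI on a log
#'   scale.
#' @method autoplot cryoclear_gee
#' @export
autoplot.cryoclear_gee <- function(object, ...) {
  df <- tibble::tibble(term = object$x_col, or = object$or,
                       lo = object$ci95[1], hi = object$ci95[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot cryoclear_experiment
#' @export
autoplot.cryoclear_experiment <- function(object, ...) {
  plot_presence_proportions(object$proportions)
}
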