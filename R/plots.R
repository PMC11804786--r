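#' Plot a residence-time distribution
#'
#' Normalized frequency histogram of streamline residence times (frequencies
#' sum to 1 over the retained streamlines).
#'
#' @param object a [residence_time()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.residence_stats <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$mid, y = .data$frequency)) +
    ggplot2::geom_col(width = diff(range(object$histogram$mid)) /
                        max(nrow(object$histogram) - 1, 1) * 0.9,
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$t_bar, linetype = 2) +
    ggplot2::labs(x = "residence time (s)", y = "normalized frequency",
                  title = sprintf("mean residence time %.3g s (%.0f%% retained)",
                                  object$t_bar, 100 * object$confidence)) +
    ggplot2::theme_minimal()
}

#' Plot upstream-downstream asymmetry differences
#'
#' @param object an [asymmetry_differences()] report.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.asymmetry_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pair, y = .data$difference)) +
    ggplot2::geom_col(fill = "coral") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$difference - .data$se,
                                        ymax = .data$difference + .data$se),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "slice pair", y = "upstream - downstream") +
    ggplot2::theme_minimal()
}

#' Plot a dissolution projection
#'
#' Porosity-change and rigidity-reduction percentages per scenario.
#'
#' @param object a [project_scenario()] projection.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dissolution_projection <- function(object, ...) {
  long <- rbind(
    tibble(label = object$label, quantity = "porosity change N (%)",
           value = object$N_percent),
    tibble(label = object$label, quantity = "rigidity reduction G (%)",
           value = object$G_percent))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}

#' Plot the kinetic-energy convergence trace of a flow run
#'
#' @param run a `coral_flow` object from [run_to_quasi_steady()].
#' @return A ggplot object.
#' @export
plot_convergence <- function(run) {
  ggplot2::ggplot(run$ke_trace, ggplot2::aes(x = .data$step, y = .data$ke)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "LBM step", y = "domain kinetic energy (lattice units)",
                  title = if (run$converged) "quasi-steady state reached"
                          else "not converged") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
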