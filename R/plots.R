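#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Pareto front in objective space
#'
#' Acrylamide (log-friendly, ug/kg) against yellowness, with the compliance
#' limit as a horizontal reference.
#'
#' @param object A `fry_front`.
#' @param limit Acrylamide reference line, ug/kg.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fry_front <- function(object, limit = 50, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$yellowness, y = .data$acrylamide)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(size = 0.8, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = limit, colour = "steelblue",
                        linetype = "dashed") +
    ggplot2::labs(x = "Yellowness (CIE-Lab b)",
                  y = expression("Acrylamide (" * mu * "g/kg)"),
                  title = attr(object, "provenance")) +
    ggplot2::theme_minimal()
}

#' Plot the feasible region as a moisture heat map
#'
#' @param region Output of [feasible_region()] (ideally with
#'   `keep_infeasible = TRUE` for context).
#' @param front Optional `fry_front` overlaid in the (t, T) plane.
#' @return A ggplot of the (t, T) plane coloured by terminal moisture.
#' @export
plot_feasible_region <- function(region, front = NULL) {
  p <- ggplot2::ggplot(dplyr::filter(region, .data$feasible),
                       ggplot2::aes(x = .data$t, y = .data$T_C)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$moisture)) +
    ggplot2::scale_fill_viridis_c(name = "Moisture") +
    ggplot2::labs(x = "Frying time (min)", y = "Oil temperature (°C)") +
    ggplot2::theme_minimal()
  if (!is.null(front)) {
    p <- p + ggplot2::geom_path(data = tibble::as_tibble(front),
                                colour = "firebrick", linewidth = 1)
  }
  p
}

#' Plot the front trace in the decision plane
#'
#' Operating points of a front in the (time, temperature) plane, coloured by
#' acrylamide compliance.
#'
#' @param front A classified `fry_front` (see [classify_front()]).
#' @return A ggplot.
#' @export
plot_front_trace <- function(front) {
  df <- tibble::as_tibble(front)
  if (!"compliant" %in% names(df)) df$compliant <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$T_C,
                                   colour = .data$compliant)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "firebrick"),
                                 na.value = "grey50",
                                 name = "Compliant") +
    ggplot2::labs(x = "Frying time (min)", y = "Oil temperature (°C)") +
    ggplot2::theme_minimal()
}

#' Plot a Monte-Carlo ensemble of fronts
#'
#' Ensemble points as a cloud with the nominal front overlaid.
#'
#' @param object A `fry_ensemble`.
#' @param limit Acrylamide reference line, ug/kg.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fry_ensemble <- function(object, limit = 50, ...) {
  pts <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$yellowness,
                                    y = .data$acrylamide)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.2) +
    ggplot2::geom_line(data = tibble::as_tibble(object$nominal),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::geom_hline(yintercept = limit, colour = "steelblue",
                        linetype = "dashed") +
    ggplot2::labs(x = "Yellowness (CIE-Lab b)",
                  y = expression("Acrylamide (" * mu * "g/kg)")) +
    ggplot2::theme_minimal()
}
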