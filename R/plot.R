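#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dose-response curve
#'
#' Relative BACH1 transcription (% of maximal) against percent of the
#' maximal inhibitor dose, one colored line per scenario if several
#' curves are bound together.
#'
#' @param object A `"dose_response_curve"` tibble (rows from several
#'   [dose_response()] calls may be combined with `dplyr::bind_rows()`).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(dose_response(build_n1(), "p38i"))
#' @export
autoplot.dose_response_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = 100 * .data$dose,
                               y = 100 * .data$phi_bach1,
                               colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "% of maximal inhibitor dose",
                  y = "BACH1 transcription (% of maximal)",
                  colour = "scenario",
                  title = paste("Topology:",
                                paste(unique(object$topology), collapse = ", "))) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot a surplus report
#'
#' Exported per-kinase surplus components and their total against percent
#' of the maximal dose, with the activation threshold as a dashed line.
#'
#' @param object A `"surplus_report"` tibble from [total_surplus()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(total_surplus(build_n1(), "4d_mapki"))
#' @export
autoplot.surplus_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("dose", "eps_raf", "eps_sig",
                                  "eps_mlk", "eps_taok", "total")],
    cols = -"dose", names_to = "component", values_to = "surplus"
  )
  theta <- attr(object, "theta", exact = TRUE)
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = 100 * .data$dose, y = .data$surplus,
                                    colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "% of maximal inhibitor dose",
                  y = "surplus (fraction of input signal)",
                  colour = NULL,
                  title = paste("Scenario:", attr(object, "scenario", exact = TRUE))) +
    ggplot2::theme_minimal()
  if (!is.null(theta)) {
    p <- p + ggplot2::geom_hline(yintercept = theta, linetype = "dashed")
  }
  p
}

#' Compare scenarios on one topology
#'
#' Convenience wrapper evaluating several scenarios on the same dose grid
#' and plotting the combined curves.
#'
#' @param topology A `network_topology`.
#' @param scenarios Character vector of preset names or list of
#'   [scenario()] objects.
#' @param doses Dose grid.
#' @param constants Constant set from [mapk_constants()].
#' @return A ggplot object.
#' @examples
#' plot_dose_response(build_n1())
#' @export
plot_dose_response <- function(topology,
                               scenarios = c("p38i", "meki", "jnki", "4d_mapki"),
                               doses = seq(0, 1, by = 0.01),
                               constants = mapk_constants()) {
  curves <- dplyr::bind_rows(lapply(scenarios, function(s) {
    dose_response(topology, s, doses, constants = constants)
  }))
  class(curves) <- c("dose_response_curve", class(tibble::tibble()))
  autoplot(curves)
}
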