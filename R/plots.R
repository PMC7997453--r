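#' @exportS3Method ggplot2::autoplot
autoplot.sim_profile <- function(object, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_h,
                                    y = .data$blood_conc_ng_ml)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "Time (h)", y = "Whole-blood concentration (ng/mL)",
      title = paste0(attr(object, "victim") %||% "victim",
                     if (!is.null(attr(object, "perpetrator"))) {
                       paste0(" + ", attr(object, "perpetrator"),
                              " (", attr(object, "mechanism"), ")")
                     } else {
                       ""
                     }),
      subtitle = attr(object, "population")
    )
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.dixon_fit <- function(object, ...) {
  lines <- object$lines
  i_min <- min(-2 * object$ki, min(object$intersections$i_intersect, na.rm = TRUE))
  grid <- tidyr::expand_grid(
    substrate_um = lines$substrate_um,
    inhibitor_um = seq(i_min, max(0, -i_min / 2), length.out = 50)
  ) |>
    dplyr::left_join(lines, by = "substrate_um") |>
    dplyr::mutate(inv_v = .data$intercept + .data$slope * .data$inhibitor_um)
  ggplot2::ggplot(grid,
                  ggplot2::aes(x = .data$inhibitor_um, y = .data$inv_v,
                               colour = factor(.data$substrate_um))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = -object$ki, linetype = "dashed") +
    ggplot2::labs(x = "Inhibitor (uM)", y = "1 / velocity",
                  colour = "Substrate (uM)",
                  title = sprintf("Dixon plot; Ki = %.3g uM", object$ki))
}

#' @exportS3Method ggplot2::autoplot
autoplot.kobs_table <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$inhibitor_um, y = .data$kobs)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Inhibitor (uM)", y = "kobs (1/min)",
                  title = "Observed inactivation rates")
  if (!is.null(fit)) {
    grid <- tibble::tibble(
      inhibitor_um = seq(0, max(object$inhibitor_um), length.out = 100)
    ) |>
      dplyr::mutate(kobs = fit$kinact * .data$inhibitor_um /
                      (fit$ki_conc + .data$inhibitor_um))
    p <- p + ggplot2::geom_line(data = grid, colour = "#d95f02")
  }
  p
}

#' Plot a DDI scenario grid as AUCR bars
#'
#' @param results A `ddi_results` tibble from [run_scenario_grid()].
#' @return A ggplot object.
#' @export
plot_aucr_grid <- function(results) {
  d <- dplyr::filter(results, .data$status == "ok",
                     .data$perpetrator != "none")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$case, y = .data$aucr,
                                  fill = .data$regimen)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::facet_grid(population ~ perpetrator) +
    ggplot2::labs(x = "Inhibition case", y = "AUC ratio",
                  title = "Predicted fold-increase in victim exposure")
}
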