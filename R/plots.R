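#' Plot finite-sample occupancy trajectories
#'
#' One line per site (light) with the seasonal mean over all sites
#' (heavy), the standard way to display smoothed occupancy trajectories
#' from a multi-season model.
#'
#' @param object A [smoothed_occupancy()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smoothed_occupancy <- function(object, ...) {
  d <- tibble::as_tibble(object)
  means <- d |>
    dplyr::group_by(.data$season) |>
    dplyr::summarise(psi_fs = mean(.data$psi_fs), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$season, y = .data$psi_fs)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$site), alpha = 0.15) +
    ggplot2::geom_line(data = means, linewidth = 1.2, colour = "#2166ac") +
    ggplot2::geom_point(data = means, size = 2, colour = "#2166ac") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "season", y = "finite-sample occupancy")
}

#' Plot subpopulation turnover and equilibrium occupancy by season
#'
#' Seasonal turnover and equilibrium occupancy per subpopulation, with the
#' seasonal mean finite-sample occupancy overlaid on the equilibrium panel
#' so departures from the stable level are visible at a glance. Dynamics
#' are not shown for the final season, where they are not estimated.
#'
#' @param object A [subpopulation_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subpop_summary <- function(object, ...) {
  d <- object$by_season |>
    tidyr::pivot_longer(cols = c("turnover", "equilibrium"),
                        names_to = "quantity", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  occ <- object$by_season |>
    dplyr::filter(is.finite(.data$equilibrium), is.finite(.data$psi_fs)) |>
    dplyr::mutate(quantity = "equilibrium")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$season, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = occ,
                        ggplot2::aes(y = .data$psi_fs),
                        shape = 2, colour = "#b2182b") +
    ggplot2::facet_grid(quantity ~ subpopulation) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "season", y = NULL)
}

#' Plot extinction-debt classification
#'
#' Subpopulations positioned by mean turnover and non-equilibrium index,
#' coloured by risk label, with the classification thresholds drawn.
#'
#' @param object A [classify_debt()] result.
#' @param thresholds The thresholds used (redrawn as guides).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.debt_assessment <- function(object,
                                     thresholds = list(turnover = c(0.25, 0.50),
                                                       non_equilibrium = 0.10),
                                     ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$non_equilibrium, y = .data$turnover,
                               colour = .data$risk_label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_hline(yintercept = thresholds$turnover, linetype = 3,
                        colour = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$subpopulation),
                       vjust = -0.9, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "non-equilibrium (occupancy - equilibrium)",
                  y = "mean turnover probability", colour = "risk")
}
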