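#' Tidy a fitted dynamic occupancy model
#'
#' Returns the coefficient table in the layout conventional for occupancy
#' analyses: one row per term with its parameter group, logit-scale
#' estimate, standard error, Wald 95% confidence interval and two-sided
#' Wald z p-value.
#'
#' @param x An `occu_fit` (or `rate_surfaces`).
#' @param conf_level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return A tibble: `group`, `term`, `estimate`, `std_error`, `conf_low`,
#'   `conf_high`, `p_value`.
#' @export
tidy.occu_fit <- function(x, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  x$term_table |>
    dplyr::mutate(
      conf_low = .data$estimate - z * .data$std_error,
      conf_high = .data$estimate + z * .data$std_error,
      p_value = 2 * pnorm(-abs(.data$estimate / .data$std_error))
    )
}

#' Glance at a fitted dynamic occupancy model
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `K`, `n_sites`, `nll`, `log_lik`,
#'   `aicc`, `converged`, `max_abs_gradient`.
#' @export
glance.occu_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$name, K = as.integer(x$K), n_sites = as.integer(x$n_sites),
    nll = x$nll, log_lik = -x$nll, aicc = x$aicc,
    converged = x$converged, max_abs_gradient = x$max_abs_gradient
  )
}

#' Coefficient plot for a fitted model
#'
#' Logit-scale estimates with Wald 95% intervals, faceted by parameter
#' group.
#'
#' @param object An `occu_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occu_fit <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)" | dplyr::n() <= 4)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high)
    ) +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "estimate (logit scale)", y = NULL,
                  title = object$spec$name)
}
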