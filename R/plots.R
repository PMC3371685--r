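#' Plot a simulated trajectory
#'
#' One facet per model population against time in days.
#'
#' @param object A `melimm_trajectory`.
#' @param log10_C Plot the melanoma cell count on a log10 axis in its own
#'   facet? Default `FALSE` (shared linear axes, free y per facet).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.melimm_trajectory <- function(object, log10_C = FALSE, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(state_vars()),
                        names_to = "population", values_to = "count") |>
    dplyr::mutate(population = factor(.data$population,
                                      levels = state_vars()))
  if (log10_C) long$count <- ifelse(long$population == "C",
                                    log10(pmax(long$count, 1)), long$count)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_days,
                                     y = .data$count)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_wrap(~population, scales = "free_y") +
    ggplot2::labs(x = "time (days)",
                  y = if (log10_C) "count (C: log10)" else "count",
                  title = "Melanoma-immune DDE trajectory") +
    ggplot2::theme_minimal()
}

#' Compare the melanoma burden across treatment arms
#'
#' @param scenarios The stacked tibble returned by [run_scenarios()].
#' @param population Which population to plot (default the melanoma burden
#'   `C`).
#' @return A ggplot object, one coloured line per arm.
#' @export
plot_scenarios <- function(scenarios, population = "C") {
  if (!all(c("time_days", "scenario", population) %in% names(scenarios))) {
    stop("scenarios must come from run_scenarios()", call. = FALSE)
  }
  ggplot2::ggplot(scenarios,
                  ggplot2::aes(x = .data$time_days,
                               y = .data[[population]],
                               colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = population,
                  colour = "treatment",
                  title = sprintf("%s under the four vaccination protocols",
                                  population)) +
    ggplot2::theme_minimal()
}

#' Plot a PRCC timecourse
#'
#' One facet per parameter, PRCC against time in days, with the dummy
#' parameter's curve overlaid in every facet as the negative control and
#' points marked where the correlation is significant.
#'
#' @param object A `prcc_timecourse`.
#' @param parameters Parameters to show (default: all but the dummy).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prcc_timecourse <- function(object, parameters = NULL, ...) {
  tbl <- tibble::as_tibble(object)
  dummy <- dplyr::filter(tbl, .data$parameter == "dummy") |>
    dplyr::select("time_days", dummy_prcc = "prcc")
  if (is.null(parameters)) {
    parameters <- setdiff(unique(tbl$parameter), "dummy")
  }
  shown <- dplyr::filter(tbl, .data$parameter %in% parameters)
  p <- ggplot2::ggplot(shown, ggplot2::aes(x = .data$time_days,
                                           y = .data$prcc)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_point(data = dplyr::filter(shown, .data$significant),
                        size = 0.6, colour = "steelblue4") +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "time (days)", y = "PRCC on C(t)",
                  title = "Time-resolved parameter sensitivity",
                  subtitle = "red: dummy parameter (negative control); points: p < 0.01") +
    ggplot2::theme_minimal()
  if (nrow(dummy) > 0) {
    p <- p + ggplot2::geom_line(data = dummy,
                                ggplot2::aes(y = .data$dummy_prcc),
                                colour = "firebrick", linewidth = 0.3)
  }
  p
}

#' Plot a Gompertz fit against its data
#'
#' @param object A `gompertz_fit`.
#' @param ... Unused.
#' @return A ggplot object with the measured counts and the fitted curve.
#' @export
autoplot.gompertz_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time_dt = seq(0, max(object$data$time_dt), length.out = 200)
  )
  grid$cells <- predict(object, grid$time_dt)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_dt,
                                            y = .data$cells)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue4") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (dt units)", y = "cells (log scale)",
                  title = "Gompertz growth fit") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
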