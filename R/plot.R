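# ggplot2 diagnostics.

#' Plot a simulated trajectory
#'
#' Faceted time courses of the liquid-phase states (sugars, biomass,
#' acetate, E2).
#'
#' @param object an `fh2_sim` or `fh2_dataset` tibble.
#' @param states column names to display.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot fh2_sim
autoplot.fh2_sim <- function(object,
                             states = c("glu_cmol_L", "xyl_cmol_L",
                                        "ara_cmol_L", "x_cmol_L",
                                        "ac_cmol_L", "e2_cmol_L"), ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "time_h",
                  dplyr::all_of(states)),
    -"time_h", names_to = "state", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL)
}

#' @rdname autoplot.fh2_sim
#' @export
#' @method autoplot fh2_dataset
autoplot.fh2_dataset <- function(object, ...) {
  p <- autoplot.fh2_sim(object, ...)
  p$layers[[1]] <- NULL
  p + ggplot2::geom_point(size = 0.8)
}

#' Plot gas productivities
#'
#' Hydrogen and CO2 volumetric productivity traces of a simulation; the
#' diauxic cases show the characteristic double peak.
#'
#' @param series an `fh2_sim` tibble.
#' @param constants optional [reactor_constants()].
#' @param gas_reference see [h2_productivity()].
#' @return A ggplot object.
#' @export
plot_productivity <- function(series, constants = NULL,
                              gas_reference = "reactor") {
  d <- dplyr::bind_rows(
    dplyr::mutate(h2_productivity(series, constants, gas_reference),
                  gas = "H2"),
    dplyr::mutate(co2_productivity(series, constants, gas_reference),
                  gas = "CO2"))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$productivity_L_h_L,
                                  colour = .data$gas)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "productivity (L/h/L)",
                  colour = NULL)
}

#' @rdname tidy.fh2_fit
#' @param object an `fh2_fit`.
#' @export
#' @method autoplot fh2_fit
autoplot.fh2_fit <- function(object, ...) {
  sim <- simulate_batch(
    replace_parameters(object$case, object$estimates),
    t_grid = sort(unique(c(0, object$data$time_h))))
  cols <- FIT_STATE_COLS[object$states]
  obs <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object$data), "time_h",
                  dplyr::all_of(unname(cols))),
    -"time_h", names_to = "state", values_to = "value")
  mod <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(sim), "time_h",
                  dplyr::all_of(unname(cols))),
    -"time_h", names_to = "state", values_to = "value")
  ggplot2::ggplot(obs, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = mod, colour = "#2166ac") +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL)
}

replace_parameters <- function(case, theta) {
  for (nm in names(theta)) case$parameters[[nm]] <- unname(theta[[nm]])
  case
}

#' @rdname rank_parameters
#' @param object an `fh2_sensitivity` tibble.
#' @param ... unused.
#' @export
#' @method autoplot fh2_sensitivity
autoplot.fh2_sensitivity <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object),
                     !is.na(.data$gamma_abs_mean))
  ggplot2::ggplot(d, ggplot2::aes(.data$parameter,
                                  .data$gamma_abs_mean)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean |Gamma|")
}
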