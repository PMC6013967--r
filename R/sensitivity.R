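# One-factor-at-a-time local sensitivity analysis.

#' Relative OFAT sensitivity of one output trace
#'
#' The pointwise sensitivity used throughout the analysis:
#' `Gamma = ((y(theta) - y(theta * (1 + delta))) / y(theta)) / delta`.
#' Note the sign convention: a parameter increase that increases the
#' output gives a negative Gamma.  For a linear map y = theta the limit is
#' -1; for y = theta^2 it is -(2 + delta).
#'
#' @param y_base output at the nominal parameter value.
#' @param y_pert output at `theta * (1 + delta)`.
#' @param delta relative perturbation.
#' @return Gamma, same length as the inputs.
#' @export
#' @examples
#' ofat_gamma(2, 2 * 1.01, delta = 0.01)  # -1 for a linear map
ofat_gamma <- function(y_base, y_pert, delta) {
  if (delta <= 0) stop_domain("delta", "must be strictly positive")
  ((y_base - y_pert) / y_base) / delta
}

#' One-factor-at-a-time sensitivity analysis of a case
#'
#' Perturbs each kinetic parameter in turn by the relative factor `delta`
#' (default 1%), re-simulates the case, and evaluates the pointwise
#' relative sensitivity [ofat_gamma()] for each tracked state at every
#' output time where the baseline is above `floor` (guarding the division
#' near zero).  Both the signed mean and the mean absolute Gamma are
#' reported; rankings use the latter.
#'
#' @param case an [case_definition()].
#' @param constants a [reactor_constants()].
#' @param params_to_probe character vector of parameter names from
#'   [kinetic_parameters()].
#' @param states_to_track names among
#'   `c("glu","xyl","ara","ac","x","h2")`; `h2` is tracked as the
#'   accumulated (off-gas) hydrogen, the quantity actually measured in a
#'   fermentation.
#' @param delta relative perturbation (> 0).
#' @param t_grid output grid for the simulations.
#' @param floor baseline magnitude below which time points are excluded.
#' @param ... passed to [simulate_batch()] (tolerances etc.).
#' @return A tibble of class `fh2_sensitivity`: one row per state x
#'   parameter with `gamma_mean`, `gamma_abs_mean`, `n_points` (rows with
#'   an identically sub-floor baseline get `NA` and a zero count rather
#'   than a silent 0).
#' @export
ofat_sensitivity <- function(case, constants = reactor_constants(),
                             params_to_probe = SENS_PARAMS,
                             states_to_track = names(SENS_STATES),
                             delta = 0.01,
                             t_grid = seq(0, case$t_end, by = 0.5),
                             floor = 1e-9, ...) {
  if (delta <= 0) stop_domain("delta", "must be strictly positive")
  bad <- setdiff(params_to_probe, names(case$parameters))
  if (length(bad))
    stop(sprintf("unknown parameter(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  states_to_track <- match.arg(states_to_track, names(SENS_STATES),
                               several.ok = TRUE)
  base <- simulate_batch(case, constants, t_grid = t_grid, ...)

  rows <- purrr::map_dfr(params_to_probe, function(pn) {
    pert_case <- case
    pert_case$parameters[[pn]] <- case$parameters[[pn]] * (1 + delta)
    pert <- simulate_batch(pert_case, constants, t_grid = t_grid, ...)
    purrr::map_dfr(states_to_track, function(sn) {
      col <- SENS_STATES[[sn]]
      yb <- base[[col]]
      yp <- pert[[col]]
      use <- abs(yb) > floor
      if (!any(use))
        return(tibble::tibble(state = sn, parameter = pn,
                              gamma_mean = NA_real_,
                              gamma_abs_mean = NA_real_, n_points = 0L))
      g <- ofat_gamma(yb[use], yp[use], delta)
      tibble::tibble(state = sn, parameter = pn, gamma_mean = mean(g),
                     gamma_abs_mean = mean(abs(g)),
                     n_points = sum(use))
    })
  })
  structure(rows, delta = delta,
            class = c("fh2_sensitivity", class(rows)))
}

#' Rank parameters by sensitivity
#'
#' Per tracked state, the probed parameters whose mean absolute Gamma
#' exceeds `threshold` (default 1%), in descending order of influence.
#'
#' @param result an [ofat_sensitivity()] result.
#' @param threshold minimal mean `|Gamma|` for a parameter to be listed.
#' @return A tibble `state`, `parameter`, `gamma_abs_mean`, `rank`
#'   (states whose parameters all fall below the threshold are absent).
#' @export
rank_parameters <- function(result, threshold = 0.01) {
  result |>
    dplyr::filter(!is.na(.data$gamma_abs_mean),
                  .data$gamma_abs_mean > threshold) |>
    dplyr::group_by(.data$state) |>
    dplyr::arrange(dplyr::desc(.data$gamma_abs_mean), .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("state", "parameter", "gamma_abs_mean", "rank")
}
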