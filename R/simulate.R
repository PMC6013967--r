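# Batch simulation and derived observables.

#' Simulate a batch fermentation
#'
#' Integrates the stiff ODE system for a case with the built-in Rosenbrock
#' solver and returns the trajectory as a tibble (one row per grid time).
#' Besides the eleven model states, the output carries the cumulative
#' washed-out hydrogen (`h2acc_mol_L`) and carbon dioxide (`co2w_cmol_L`),
#' the cumulative decayed biomass (`xdead_cmol_L`) and the instantaneous
#' headspace outflow (`q_gas_L_h`).
#'
#' @param case an [case_definition()].
#' @param constants a [reactor_constants()].
#' @param t_grid output times, h (strictly increasing, starting at 0).
#' @param q_gas_mode headspace outflow model; see [rhs()].
#' @param rtol,atol relative/absolute solver tolerances.
#' @param max_steps integration step budget.
#' @return A tibble of class `fh2_sim` with `time_h`, state and bookkeeping
#'   columns; attributes `case`, `constants`, `q_gas_mode` and `solver`
#'   (diagnostics).
#' @export
#' @examples
#' sim <- simulate_batch(default_case("case1"), t_grid = seq(0, 40, 1))
#' dplyr::glimpse(sim)
simulate_batch <- function(case, constants = reactor_constants(),
                           t_grid = seq(0, case$t_end, by = 0.25),
                           q_gas_mode = c("n2_plus_product", "n2_only"),
                           rtol = 1e-8, atol = 1e-10, max_steps = 5e6) {
  stopifnot(inherits(case, "fh2_case"), inherits(constants, "fh2_constants"))
  q_gas_mode <- match.arg(q_gas_mode)
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("`t_grid` must be strictly increasing with at least two points",
         call. = FALSE)
  if (max(t_grid) > case$t_end + 1e-9)
    stop("`t_grid` extends beyond the case horizon t_end", call. = FALSE)

  y0 <- c(as.numeric(case$initial_state[STATE_VARS]), 0, 0, 0)
  res <- simulate_cpp(y0, t_grid, kin_vector(case$parameters, case$yields),
                      cons_vector(constants), case$diauxic_enabled,
                      ifelse(q_gas_mode == "n2_plus_product", 0L, 1L),
                      rtol, atol, max_steps)
  y <- res$y
  colnames(y) <- c(unname(STATE_COLS), unname(AUX_COLS))
  out <- tibble::as_tibble(as.data.frame(y))
  out <- tibble::add_column(out, time_h = t_grid, .before = 1)
  out$q_gas_L_h <- as.numeric(res$q_gas)
  structure(out,
            case = case, constants = constants, q_gas_mode = q_gas_mode,
            solver = list(rtol = rtol, atol = atol,
                          n_accept = res$n_accept, n_reject = res$n_reject),
            class = c("fh2_sim", class(out)))
}

sim_constants <- function(series, constants) {
  if (!is.null(constants)) return(constants)
  cs <- attr(series, "constants")
  if (is.null(cs)) reactor_constants() else cs
}

#' Volumetric gas productivities
#'
#' Hydrogen (or CO2) evolution rate leaving the reactor, expressed as gas
#' volume per hour per litre of liquid.  Computed from the headspace
#' outflow: `q_gas * (conc * R * T) / V_liq`, where `conc * R * T` is the
#' mole fraction of the gas at 1 atm.  With `gas_reference = "stp"` volumes
#' are rescaled from reactor temperature to 273.15 K.
#'
#' @param series an `fh2_sim` tibble (or any tibble with the gas and
#'   `q_gas_L_h` columns).
#' @param constants a [reactor_constants()]; defaults to the attribute
#'   stored on `series`.
#' @param gas_reference reference condition for the reported gas volumes.
#' @return A tibble `time_h`, `productivity_L_h_L`.
#' @export
h2_productivity <- function(series, constants = NULL,
                            gas_reference = c("reactor", "stp")) {
  gas_productivity(series, "h2g_M", constants, match.arg(gas_reference))
}

#' @rdname h2_productivity
#' @export
co2_productivity <- function(series, constants = NULL,
                             gas_reference = c("reactor", "stp")) {
  gas_productivity(series, "co2g_cmol_L", constants,
                   match.arg(gas_reference))
}

gas_productivity <- function(series, col, constants, gas_reference) {
  cs <- sim_constants(series, constants)
  scale <- if (gas_reference == "stp") 273.15 / cs$T else 1
  tibble::tibble(
    time_h = series$time_h,
    productivity_L_h_L = series$q_gas_L_h *
      (series[[col]] * cs$R_gas * cs$T) / cs$V_liq * scale)
}

#' Cumulative hydrogen leaving the reactor
#'
#' Trapezoidal time integral of `q_gas * H2,g / V_liq` (mol per litre of
#' liquid), i.e. the hydrogen carried out with the off-gas.
#'
#' @inheritParams h2_productivity
#' @return A tibble `time_h`, `h2_accumulated_mol_L` (non-decreasing).
#' @export
h2_accumulated <- function(series, constants = NULL) {
  cs <- sim_constants(series, constants)
  flux <- series$q_gas_L_h * series$h2g_M / cs$V_liq
  tibble::tibble(time_h = series$time_h,
                 h2_accumulated_mol_L = cumtrapz(series$time_h, flux))
}

cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum(0.5 * diff(t) * (y[-1] + y[-n])))
}

#' Carbon balance of a trajectory
#'
#' Percent of the carbon initially present as sugar that is found at the
#' final time point in biomass, acetate, the CO2 pools (dissolved, ionic,
#' headspace, washed out) and residual sugar.  With
#' `include_decayed = TRUE` (default) biomass carbon lost to cell death is
#' counted as biomass, which closes the balance exactly when
#' `Y_ac + Y_co2 = 1`.
#'
#' @param series an `fh2_sim` tibble.
#' @param constants a [reactor_constants()]; defaults to the stored
#'   attribute.
#' @param include_decayed count cumulatively decayed biomass as biomass
#'   carbon.
#' @return Carbon recovery, percent.
#' @export
carbon_balance <- function(series, constants = NULL,
                           include_decayed = TRUE) {
  cs <- sim_constants(series, constants)
  first <- series[1, ]
  last <- series[nrow(series), ]
  sugar0 <- first$glu_cmol_L + first$xyl_cmol_L + first$ara_cmol_L
  if (sugar0 <= 0)
    stop("carbon balance undefined: no sugar at t = 0", call. = FALSE)
  vr <- cs$V_gas / cs$V_liq
  pool <- function(r) {
    r$glu_cmol_L + r$xyl_cmol_L + r$ara_cmol_L + r$x_cmol_L + r$ac_cmol_L +
      r$co2aq_cmol_L + r$co2sol_cmol_L + vr * r$co2g_cmol_L +
      r$co2w_cmol_L + if (include_decayed) r$xdead_cmol_L else 0
  }
  100 * pool(last) / sugar0
}

# total carbon inventory per row (used by conservation tests): includes the
# non-sugar pools present at t = 0 as well.
total_carbon <- function(series, constants = NULL) {
  cs <- sim_constants(series, constants)
  vr <- cs$V_gas / cs$V_liq
  series$glu_cmol_L + series$xyl_cmol_L + series$ara_cmol_L +
    series$x_cmol_L + series$ac_cmol_L + series$co2aq_cmol_L +
    series$co2sol_cmol_L + vr * series$co2g_cmol_L + series$co2w_cmol_L +
    series$xdead_cmol_L
}

#' Locate local maxima of a trace
#'
#' Peak finder used to count hydrogen-productivity maxima: a point is a
#' peak when it exceeds its neighbours and its topographic prominence
#' (height above the higher of the two flanking minima separating it from
#' larger peaks) exceeds `min_prominence` times the global maximum.
#'
#' @param y numeric trace.
#' @param min_prominence minimal relative prominence (fraction of
#'   `max(y)`).
#' @return Integer vector of peak indices.
#' @export
find_peaks <- function(y, min_prominence = 0.05) {
  n <- length(y)
  if (n < 3 || max(y) <= 0) return(integer(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # walk left/right until a higher point or the boundary; prominence is
    # height above the higher of the two interval minima
    left <- y[seq_len(i - 1)]
    right <- y[seq((i + 1), n)]
    lhigher <- which(left > y[i])
    rhigher <- which(right > y[i])
    lmin <- min(left[seq(from = if (length(lhigher)) max(lhigher) else 1,
                         to = i - 1)])
    rmin <- min(right[seq_len(if (length(rhigher)) min(rhigher) else
      length(right))])
    prom <- y[i] - max(lmin, rmin)
    keep[k] <- prom > min_prominence * max(y)
  }
  cand[keep]
}
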