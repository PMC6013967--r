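# Synthetic batch-fermentation datasets: the study's fermentor time series
# are unpublished, so every downstream module is exercised against data
# generated from known parameters.

#' Measurement-noise model
#'
#' Multiplicative Gaussian noise on the relative scale (truncated at zero)
#' plus an optional additive floor component for near-zero readings.  The
#' 5% default is a conservative reading of the replicate standard
#' deviations of the underlying experiments (~1-2% on initial sugar
#' measurements).
#'
#' @param relative_sd multiplicative (relative) standard deviation.
#' @param floor_sd additive standard deviation near zero (same units as
#'   the state).
#' @param seed integer seed; the same seed reproduces the identical
#'   dataset.
#' @return Object of class `fh2_noise`.
#' @export
noise_model <- function(relative_sd = 0.05, floor_sd = 0, seed = NULL) {
  check_nonneg(relative_sd, "relative_sd")
  check_nonneg(floor_sd, "floor_sd")
  structure(list(relative_sd = relative_sd, floor_sd = floor_sd,
                 seed = seed), class = "fh2_noise")
}

#' Apply measurement noise to a value vector
#'
#' `x * (1 + relative_sd * z1) + floor_sd * z2`, truncated at zero.
#' Exported so the noise structure itself is testable without re-running a
#' simulation.
#'
#' @param x clean values.
#' @param noise an [noise_model()].
#' @return Noisy values, same length, all `>= 0`.
#' @export
add_measurement_noise <- function(x, noise = noise_model()) {
  y <- x * (1 + noise$relative_sd * stats::rnorm(length(x))) +
    noise$floor_sd * stats::rnorm(length(x))
  pmax(y, 0)
}

#' Generate a synthetic fermentation dataset
#'
#' Simulates a case, optionally prepends a lag phase by shifting the
#' trajectory in time (biomass and all other states held at their initial
#' values before the lag ends, matching how lag phases are excluded from
#' kinetic modelling rather than modelled), samples it on a regular grid,
#' and applies multiplicative measurement noise.  Provenance (true
#' parameters, seed, noise settings) is stored in attributes and written
#' to the CSV header by [write_timeseries()].
#'
#' @param case an [case_definition()].
#' @param constants a [reactor_constants()].
#' @param interval sampling interval, h (fermentor sampling is every
#'   1-2 h; default 1.5).
#' @param t_end last sample time, h.
#' @param noise an [noise_model()].
#' @param lag_h imposed lag duration, h.
#' @param ... passed to [simulate_batch()].
#' @return Tibble of class `fh2_dataset` shaped like a [simulate_batch()]
#'   result (including the `h2acc_mol_L` bookkeeping column).
#' @export
#' @examples
#' d <- generate_case_dataset(default_case("case1"), interval = 4,
#'                            t_end = 20, noise = noise_model(seed = 1))
generate_case_dataset <- function(case, constants = reactor_constants(),
                                  interval = 1.5, t_end = case$t_end,
                                  noise = noise_model(), lag_h = 0, ...) {
  check_pos(interval, "interval")
  check_nonneg(lag_h, "lag_h")
  t_sample <- seq(0, t_end, by = interval)
  # simulation clock: sample times after subtracting the lag
  t_model <- pmax(t_sample - lag_h, 0)
  t_grid <- sort(unique(c(0, t_model)))
  sim <- simulate_batch(case, constants, t_grid = t_grid, ...)
  rows <- match(t_model, t_grid)
  out <- sim[rows, , drop = FALSE]
  out$time_h <- t_sample

  # cumulative off-gas pools are kept: they stand for the integrated
  # off-gas GC measurements and are required for the H2/CO2 yield
  # accounting
  noisy_cols <- unname(c(STATE_COLS, AUX_COLS[c("h2out", "co2out")]))
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(noise$seed)
  }
  if (noise$relative_sd > 0 || noise$floor_sd > 0)
    for (cl in noisy_cols) out[[cl]] <- add_measurement_noise(out[[cl]],
                                                              noise)
  out <- dplyr::select(out, -"xdead_cmol_L", -"q_gas_L_h")
  structure(out, case = case, constants = constants, noise = noise,
            lag_h = lag_h,
            provenance = list(case = case$name, seed = noise$seed,
                              relative_sd = noise$relative_sd,
                              floor_sd = noise$floor_sd, lag_h = lag_h,
                              true_parameters = unclass(case$parameters),
                              true_yields = unclass(case$yields)),
            class = c("fh2_dataset", "tbl_df", "tbl", "data.frame"))
}
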