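# Shared fixtures: coarse grids keep the suite fast; tolerances stay at the
# solver defaults unless a test probes convergence itself.

coarse_grid <- function(case, by = 1) seq(0, case$t_end, by = by)

# a small phase-I-only toy case for cheap property checks
toy_case <- function(...) {
  case_definition(
    name = "toy",
    initial_state = model_state(glu = 0.2, x = 0.002),
    parameters = kinetic_parameters(km = 1, km2 = 0, r_cd = 0.01,
                                    alpha = 0),
    yields = yield_set(Y_x = 0.2, Y_ac = 2 / 3 * 0.99, Y_h2 = 0.5,
                       Y_co2 = 1 / 3 * 1.02),
    diauxic_enabled = FALSE, ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
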