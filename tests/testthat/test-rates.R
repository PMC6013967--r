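# Rate laws, stoichiometry, speciation and transfer terms.

test_that("Monod uptake: saturation, half-saturation, frozen evaluation", {
  # saturation limit and half-saturation
  expect_equal(monod_uptake_rate(0.54, S = 1e9, Ks = 2e-4, X = 1), 0.54,
               tolerance = 1e-9)
  expect_equal(monod_uptake_rate(0.54, S = 2e-4, Ks = 2e-4, X = 1), 0.27)
  # mixture-case start values (glucose-free xylose term), frozen hand value
  expect_equal(monod_uptake_rate(0.54, S = 0.10, Ks = 2e-4, X = 0.0016),
               0.0008622754491017965, tolerance = 1e-12)
  expect_equal(monod_uptake_rate(0.54, S = 0, Ks = 2e-4, X = 1), 0)
  expect_equal(monod_uptake_rate(0.54, S = 0.1, Ks = 2e-4, X = 0), 0)
  # E_factor scales linearly (phase-II form)
  expect_equal(monod_uptake_rate(1.26, S = 0.2, Ks = 0.01, X = 0.01,
                                 E_factor = 0.5),
               0.5 * monod_uptake_rate(1.26, S = 0.2, Ks = 0.01, X = 0.01))
  expect_error(monod_uptake_rate(0.54, S = -1, Ks = 2e-4, X = 1), "S")
  expect_error(monod_uptake_rate(-0.1, S = 1, Ks = 2e-4, X = 1), "km")
})

test_that("Hill synthesis rate: half-saturation, zeros, frozen value", {
  expect_equal(hill_synthesis_rate(0.6, Glu = 0.001, Ks_E2 = 0.001, n = 2,
                                   X = 1), 0.30)
  expect_equal(hill_synthesis_rate(0.6, Glu = 0, Ks_E2 = 0.001, n = 2,
                                   X = 1), 0)
  expect_equal(hill_synthesis_rate(0.6, Glu = 0.1, Ks_E2 = 0.001, n = 2,
                                   X = 1, u = 0), 0)
  # hydrolysate-case start values, frozen hand value
  expect_equal(hill_synthesis_rate(0.64, Glu = 0.26, Ks_E2 = 0.001, n = 2,
                                   X = 0.0058, u = 0.5),
               0.0018559725447848403, tolerance = 1e-12)
  expect_error(hill_synthesis_rate(0.6, Glu = -0.1, Ks_E2 = 1e-3, n = 2,
                                   X = 1), "Glu")
})

test_that("cybernetic weights follow the matching law and stay in [0,1]", {
  w <- cybernetic_weights(2, 1)
  expect_equal(w, list(v1 = 1, v2 = 0.5, u = 1 / 3))
  expect_equal(cybernetic_weights(0, 5), list(v1 = 0, v2 = 1, u = 1))
  expect_equal(cybernetic_weights(0, 0), list(v1 = 1, v2 = 1, u = 0))
  # property sweep: bounds and max(v1, v2) = 1 when not degenerate
  set.seed(42)
  for (i in 1:200) {
    a <- stats::runif(1, 0, 10)
    b <- stats::runif(1, 0, 10)
    w <- cybernetic_weights(a, b)
    expect_true(all(unlist(w) >= 0 & unlist(w) <= 1))
    expect_equal(max(w$v1, w$v2), 1)
  }
})

test_that("acid-base rate vanishes exactly at speciation equilibrium", {
  cs <- reactor_constants()
  frac <- 10^(cs$pH - cs$pK1) + 10^(2 * cs$pH - cs$pK1 - cs$pK2)
  for (c_aq in c(1e-6, 0.01, 0.3)) {
    r <- acid_base_rate(c_aq, c_aq * frac, cs)
    expect_lt(abs(r) / (cs$k_AB * c_aq * frac), 1e-12)
  }
  # frozen forward-rate value at pH 6.5, pK1 6.3, pK2 10.25
  expect_equal(acid_base_rate(0.01, 0, cs), 158.517503075424,
               tolerance = 1e-12)
  expect_equal(acid_base_rate(0, 0.01, cs), -100)
})

test_that("partial pressure is the ideal-gas law in Pa", {
  cs <- reactor_constants()
  expect_equal(partial_pressure(1 / (cs$R_gas * cs$T), cs), 101325)
  expect_equal(partial_pressure(0, cs), 0)
  expect_equal(partial_pressure(0.001, cs), 2853.199427925,
               tolerance = 1e-12)
})

test_that("gas transfer vanishes at Henry equilibrium and scales with kla", {
  cs <- reactor_constants()
  p <- 5e4
  expect_equal(gas_transfer_rate(0.44, p * cs$KH_h2, p, cs$KH_h2), 0)
  expect_equal(gas_transfer_rate(0.44, 1e-4, 0, cs$KH_h2), 4.4e-5)
  expect_equal(gas_transfer_rate(0, 1e-4, 1e4, cs$KH_h2), 0)
})

test_that("CO2 kLa power law reproduces the reference sparging point", {
  expect_equal(kla_co2_from_sparging(6), 5.85)
  expect_equal(kla_co2_from_sparging(0), 0)
  expect_equal(kla_co2_from_sparging(12), 8.0469196361175,
               tolerance = 1e-12)
})

test_that("catabolic stoichiometry: yields, H2 ceiling, redox closure", {
  ys <- stoichiometric_yields()
  expect_equal(ys$Y_ac, 2 / 3)
  expect_equal(ys$Y_h2, 2 / 3)
  expect_equal(ys$Y_co2, 1 / 3)
  expect_equal(attr(ys, "h2_per_hexose"), 4)
  expect_true(attr(ys, "carbon_closed"))
  # degree-of-reduction balance: 4 per cmol sugar = acetate + H2 electrons
  expect_identical(2 / 3 * 4 + 2 / 3 * 2, 4)
})

test_that("competitive inhibition factor and apparent Ks", {
  expect_equal(competitive_inhibition_factor(0, 1), 1)
  expect_equal(competitive_inhibition_factor(3, 3), 2)
  expect_error(competitive_inhibition_factor(1, 0), "K_I")
  # 18-fold apparent increase interprets the hydrolysate glucose Ks
  expect_equal(apparent_Ks(0.01, 18), 0.18)
})
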