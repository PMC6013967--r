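# Assembly of the right-hand side, and agreement between the R reference
# implementation and the compiled solver core.

cs <- reactor_constants()

test_that("substrate-free state decays: dX = -r_cd*X, dE2 = -beta*E2", {
  case <- default_case("case3")
  st <- model_state(x = 0.02, e2 = 0.01)
  d <- rhs(0, st, case, cs)$dydt
  expect_equal(d[["x"]], -case$parameters$r_cd * 0.02)
  expect_equal(d[["e2"]], -case$parameters$beta * 0.01)
  expect_equal(d[["glu"]], 0)
  expect_equal(d[["ac"]], 0)
})

test_that("simultaneous Henry + carbonate equilibrium is a fixed point", {
  case <- default_case("case3")
  frac <- 10^(cs$pH - cs$pK1) + 10^(2 * cs$pH - cs$pK1 - cs$pK2)
  h2g <- 0.002
  co2g <- 0.004
  co2aq <- partial_pressure(co2g, cs) * cs$KH_co2
  st <- model_state(h2aq = partial_pressure(h2g, cs) * cs$KH_h2,
                    co2aq = co2aq, co2sol = co2aq * frac,
                    h2g = h2g, co2g = co2g)
  d <- rhs(0, st, case, cs)$dydt
  # transfer and speciation rates vanish; only washout drains the headspace
  expect_equal(d[["h2aq"]], 0, tolerance = 1e-15)
  expect_equal(d[["co2aq"]], 0, tolerance = 1e-12)
  expect_equal(d[["co2sol"]], 0, tolerance = 1e-12)
  expect_equal(d[["h2g"]], -h2g * cs$N2_sparge / cs$V_gas)
})

test_that("mixture-case initial derivatives match a hand-assembled oracle", {
  case <- default_case("case3")
  st <- case$initial_state
  d <- rhs(0, st, case, cs)$dydt
  # oracle assembled from first principles with the start values
  X <- 0.0016; glu <- 0.28; xyl <- 0.10; ara <- 0.012; e2 <- 1e-7
  a <- 0.54 * xyl / (xyl + 2e-4) * X             # kinetic xylose rate
  b <- 0.54 * e2 * glu / (glu + 0.01) * X        # kinetic E2-glucose rate
  v1 <- a / max(a, b); v2 <- b / max(a, b); u <- b / (a + b)
  r_glu <- 0.54 * glu / (glu + 0.01) * X * v1
  r_xyl <- a * v1
  r_ara <- 0.54 * ara / (ara + 0.026) * X * v1
  r_glu2 <- b * v2
  tot <- r_glu + r_glu2 + r_xyl + r_ara
  expect_equal(d[["glu"]], -r_glu - r_glu2, tolerance = 1e-12)
  expect_equal(d[["xyl"]], -r_xyl, tolerance = 1e-12)
  expect_equal(d[["ara"]], -r_ara, tolerance = 1e-12)
  expect_equal(d[["x"]], 0.21 * tot - 0.027 * X, tolerance = 1e-12)
  expect_equal(d[["ac"]], 0.79 * 0.62 * tot, tolerance = 1e-12)
  expect_equal(d[["h2aq"]], 0.79 * 0.53 * tot, tolerance = 1e-12)
  # signs: sugars fall, products rise
  expect_lt(d[["glu"]], 0)
  expect_lt(d[["xyl"]], 0)
  expect_gt(d[["ac"]], 0)
  # E2 synthesis: Hill term times the allocation weight
  expect_equal(d[["e2"]],
               0.6 * glu^2 / (glu^2 + 0.001^2) * X * u - 0.05 * e2 -
                 e2 * r_glu2, tolerance = 1e-12)
})

test_that("diauxic switch off reduces to a pure multi-substrate Monod model", {
  case <- default_case("case3")
  mono <- case
  mono$diauxic_enabled <- FALSE
  mono$initial_state[["e2"]] <- 0
  st <- model_state(glu = 0.2, xyl = 0.05, ara = 0.01, x = 0.01)
  d <- rhs(0, st, mono, cs)$dydt
  p <- case$parameters
  expect_equal(d[["glu"]],
               -monod_uptake_rate(p$km, 0.2, p$Ks_glu, 0.01))
  expect_equal(d[["e2"]], 0)
  r <- rhs(0, st, mono, cs)$rates
  expect_equal(unname(r[["rho_glu2"]]), 0)
  expect_equal(unname(r[["rho_E"]]), 0)
})

test_that("R reference and compiled right-hand sides agree", {
  set.seed(7)
  for (nm in c("case1", "case3", "case4")) {
    case <- default_case(nm)
    kin <- fermh2:::kin_vector(case$parameters, case$yields)
    cv <- fermh2:::cons_vector(cs)
    for (i in 1:25) {
      st <- stats::runif(11, 0, 0.3)
      names(st) <- fermh2:::STATE_VARS
      st[["e2"]] <- stats::runif(1, 0, 0.4)
      y14 <- c(st, h2out = 0, co2out = 0, xdead = 0)
      r_cpp <- fermh2:::rhs_point_cpp(unname(y14), kin, cv,
                                      case$diauxic_enabled, 0L)
      r_r <- rhs(0, st, case, cs)
      expect_equal(unname(r_cpp$dydt), unname(r_r$dydt),
                   tolerance = 1e-12)
      expect_equal(r_cpp$q_gas, r_r$q_gas, tolerance = 1e-12)
    }
  }
})

test_that("non-finite states are rejected with a timestamped error", {
  case <- default_case("case3")
  st <- case$initial_state
  st[["glu"]] <- NaN
  expect_error(rhs(12.5, st, case, cs), "12.5")
})
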