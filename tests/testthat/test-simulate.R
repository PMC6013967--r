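# Trajectory-level behaviour of the integrator and derived observables.

test_that("mixture case: xylose depleted early while glucose persists", {
  sim <- simulate_batch(default_case("case3"),
                        t_grid = coarse_grid(default_case("case3"), 0.25))
  xyl0 <- sim$xyl_cmol_L[1]
  t_dep <- sim$time_h[which(sim$xyl_cmol_L < 0.01 * xyl0)[1]]
  expect_gt(t_dep, 8)
  expect_lt(t_dep, 25)
  glu_at_dep <- sim$glu_cmol_L[sim$time_h == t_dep]
  expect_gt(glu_at_dep, 0.5 * sim$glu_cmol_L[1])
  # all sugar trajectories non-increasing, accumulated H2 non-decreasing
  expect_true(all(diff(sim$glu_cmol_L) <= 1e-12))
  expect_true(all(diff(sim$xyl_cmol_L) <= 1e-12))
  expect_true(all(diff(sim$ara_cmol_L) <= 1e-12))
  expect_true(all(diff(sim$h2acc_mol_L) >= -1e-12))
})

test_that("sugar-free start: biomass decays exponentially, no products", {
  case <- default_case("case1")
  case$initial_state <- model_state(x = 0.01)
  sim <- simulate_batch(case, t_grid = seq(0, 40, 1))
  expect_equal(sim$x_cmol_L, 0.01 * exp(-0.0027 * sim$time_h),
               tolerance = 1e-6)
  expect_true(all(sim$ac_cmol_L == 0))
  expect_true(all(sim$h2acc_mol_L == 0))
})

test_that("carbon is conserved to <= 0.1% when yields close the balance", {
  for (nm in c("case3", "case1")) {
    case <- default_case(nm)
    if (nm == "case1") {
      # force closure: keep Y_x, rescale catabolic split to sum to one
      ys <- case$yields
      s <- ys$Y_ac + ys$Y_co2
      case$yields <- yield_set(ys$Y_x, ys$Y_ac / s, ys$Y_h2, ys$Y_co2 / s)
    }
    sim <- simulate_batch(case, t_grid = coarse_grid(case, 0.5))
    tc <- fermh2:::total_carbon(sim)
    expect_lt(max(abs(tc - tc[1])) / tc[1], 1e-3)
  }
})

test_that("open carbon balance shows exactly the configured deficit", {
  # Y_ac + Y_co2 = 0.9: 10% of catabolised sugar carbon leaves the books
  case <- toy_case()
  case$yields <- yield_set(Y_x = 0.2, Y_ac = 0.6, Y_h2 = 0.5, Y_co2 = 0.3)
  sim <- simulate_batch(case, t_grid = seq(0, 80, 0.5))
  consumed <- sim$glu_cmol_L[1] - sim$glu_cmol_L[nrow(sim)]
  tc <- fermh2:::total_carbon(sim)
  deficit <- tc[1] - tc[length(tc)]
  expect_equal(deficit, (1 - 0.2) * (1 - 0.9) * consumed,
               tolerance = 1e-3)
})

test_that("carbon balance reporting", {
  case <- default_case("case3")
  sim <- simulate_batch(case, t_grid = coarse_grid(case, 0.5))
  cb <- carbon_balance(sim)
  # initial acetate + biomass carbon pushes recovery slightly above 100%
  expect_gt(cb, 100)
  expect_lt(cb, 105)
  empty <- default_case("case1")
  empty$initial_state <- model_state(x = 0.01)
  sim0 <- simulate_batch(empty, t_grid = seq(0, 10, 1))
  expect_error(carbon_balance(sim0), "no sugar")
})

test_that("solver converges: 10x tighter tolerance moves endpoint < 0.01%", {
  case <- default_case("case4")
  g <- seq(0, 80, 2)
  # endpoint error measured against each state's trajectory scale (several
  # pools decay to ~atol by t_end, where a pointwise relative error is
  # meaningless)
  a <- simulate_batch(case, t_grid = g, rtol = 1e-8, atol = 1e-12)
  b <- simulate_batch(case, t_grid = g, rtol = 1e-9, atol = 1e-13)
  cols <- setdiff(names(a), "time_h")
  rel <- vapply(cols, function(cl)
    abs(a[[cl]][nrow(a)] - b[[cl]][nrow(b)]) / max(abs(b[[cl]]), 1e-12),
    numeric(1))
  expect_lt(max(rel), 1e-4)
})

test_that("H2 productivity and accumulation identities", {
  cs <- reactor_constants()
  case <- default_case("case3")
  sim <- simulate_batch(case, t_grid = coarse_grid(case, 0.25))
  p <- h2_productivity(sim)
  # single-point identity: q_gas * mole fraction / V_liq
  i <- 120
  expect_equal(p$productivity_L_h_L[i],
               sim$q_gas_L_h[i] * sim$h2g_M[i] * cs$R_gas * cs$T /
                 cs$V_liq)
  expect_true(all(p$productivity_L_h_L >= 0))
  # STP reference shrinks volumes by 273.15/T
  pstp <- h2_productivity(sim, gas_reference = "stp")
  expect_equal(pstp$productivity_L_h_L, p$productivity_L_h_L * 273.15 /
                 cs$T)
  # trapezoidal accumulation agrees with the exact integrated pool
  acc <- h2_accumulated(sim)
  expect_true(all(diff(acc$h2_accumulated_mol_L) >= -1e-15))
  expect_equal(acc$h2_accumulated_mol_L[nrow(sim)],
               sim$h2acc_mol_L[nrow(sim)], tolerance = 2e-3)
  # mass balance: H2 produced = (1-Yx)*Yh2 * sugar consumed
  n <- nrow(sim)
  h2_total <- sim$h2acc_mol_L[n] + sim$h2aq_M[n] +
    cs$V_gas / cs$V_liq * sim$h2g_M[n]
  consumed <- with(sim, glu_cmol_L[1] + xyl_cmol_L[1] + ara_cmol_L[1] -
                     glu_cmol_L[n] - xyl_cmol_L[n] - ara_cmol_L[n])
  expect_rel_equal(h2_total, (1 - 0.21) * 0.53 * consumed, 0.01)
})

test_that("diauxic machinery produces the two-peak H2 signature", {
  case <- default_case("case4")
  sim <- simulate_batch(case)
  p <- h2_productivity(sim)
  expect_identical(length(find_peaks(p$productivity_L_h_L)), 2L)
  # removing E2 synthesis abolishes the second peak
  noind <- case
  noind$parameters$alpha <- 0
  p0 <- h2_productivity(simulate_batch(noind))
  expect_identical(length(find_peaks(p0$productivity_L_h_L)), 1L)
})

test_that("glucose uptake dips after xylose depletion, then rises", {
  sim <- simulate_batch(default_case("case4"))
  rate <- -diff(sim$glu_cmol_L) / diff(sim$time_h)
  tmid <- sim$time_h[-1]
  t_dep <- sim$time_h[which(sim$xyl_cmol_L < 0.01 * 0.11)[1]]
  t_gone <- sim$time_h[which(sim$glu_cmol_L < 0.01 * 0.26)[1]]
  win <- tmid > t_dep & tmid < t_gone
  pre <- max(rate[tmid <= t_dep])
  trough <- min(rate[win])
  late <- max(rate[win][seq(which.min(rate[win]), sum(win))])
  expect_lt(trough, 0.5 * pre)   # a genuine dip against the phase-I rate
  expect_gt(late, 2 * trough)    # followed by a clear second rise
})

test_that("q_gas modes differ only by the product-gas contribution", {
  case <- default_case("case3")
  g <- seq(0, 40, 1)
  a <- simulate_batch(case, t_grid = g, q_gas_mode = "n2_plus_product")
  b <- simulate_batch(case, t_grid = g, q_gas_mode = "n2_only")
  expect_true(all(a$q_gas_L_h >= 6 - 1e-12))
  expect_true(all(b$q_gas_L_h == 6))
  expect_gt(max(a$q_gas_L_h), 6.5)
})

test_that("grid validation", {
  case <- default_case("case1")
  expect_error(simulate_batch(case, t_grid = c(0, 2, 1)),
               "strictly increasing")
  expect_error(simulate_batch(case, t_grid = seq(0, 100, 1)), "t_end")
})
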