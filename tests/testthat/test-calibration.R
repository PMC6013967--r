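# Least-squares calibration: residuals, LM fitting, confidence intervals.

test_that("residuals vanish on self-generated data and respect weights", {
  case <- default_case("case3")
  d <- generate_case_dataset(case, interval = 4, t_end = 40,
                             noise = noise_model(0, 0, NULL))
  th <- c(km = case$parameters$km, alpha = case$parameters$alpha)
  r <- objective_residuals(th, d, case)
  expect_lt(sqrt(sum(r^2)), 1e-6)
  # constant shift in one state appears as -c/weight in that block
  d2 <- d
  d2$ac_cmol_L <- d2$ac_cmol_L + 0.05
  w <- c(glu = 1, xyl = 1, ara = 1, x = 1, ac = 1, h2acc = 1)
  r2 <- objective_residuals(th, d2, case, weights = w)
  blocks <- attr(r2, "state")
  expect_equal(unique(round(r2[blocks == "ac"], 9)), -0.05)
  expect_lt(max(abs(r2[blocks == "glu"])), 1e-7)
  # default weights make blocks dimensionless and comparable
  r3 <- objective_residuals(th, d2, case)
  expect_equal(max(abs(r3[blocks == "ac"])),
               0.05 / max(abs(d2$ac_cmol_L)), tolerance = 1e-6)
  expect_error(objective_residuals(c(bogus = 1), d, case), "bogus")
})

test_that("single-rate recovery on noiseless single-sugar data is exact", {
  case <- default_case("case1")
  d <- generate_case_dataset(case, noise = noise_model(0, 0, NULL))
  ft <- fit_parameters(d, case, "km", x0 = c(km = 1.5))
  expect_true(ft$converged)
  expect_rel_equal(ft$estimates[["km"]], 2.4, 1e-3)
  expect_gt(min(ft$r_squared$r_squared), 0.999)
})

test_that("empty free set returns the benchmark residual norm unchanged", {
  case <- default_case("case1")
  d <- generate_case_dataset(case, interval = 4, t_end = 40,
                             noise = noise_model(0, 0, NULL))
  ft <- fit_parameters(d, case, character(0))
  expect_identical(ft$n_params, 0L)
  expect_lt(ft$residual_norm, 1e-10)
})

test_that("three-parameter mixture fit: identifiable directions recovered", {
  case <- default_case("case3")
  d <- generate_case_dataset(case, noise = noise_model(0, 0, NULL))
  ft <- fit_parameters(d, case, c("km", "km2", "alpha"),
                       x0 = c(km = 0.38, km2 = 0.38, alpha = 0.42))
  # km and the product km2*alpha are identified to < 0.1%; km2 and alpha
  # individually sit on a near-exact scaling ridge (E2 is unobserved)
  expect_rel_equal(ft$estimates[["km"]], 0.54, 1e-3)
  expect_rel_equal(ft$estimates[["km2"]] * ft$estimates[["alpha"]],
                   0.54 * 0.6, 1e-3)
})

test_that("fit moves benchmark start values toward the generating truth", {
  case <- default_case("case3")
  d <- generate_case_dataset(case, interval = 2,
                             noise = noise_model(0, 0, NULL))
  x0 <- c(km = 0.35, r_cd = 0.014, kla_h2 = 0.26)
  ft <- fit_parameters(d, case, names(x0), x0 = x0,
                       control = list(maxit = 40), rtol = 1e-6,
                       atol = 1e-9)
  truth <- c(km = 0.54, r_cd = 0.027, kla_h2 = 0.44)
  for (nm in names(x0)) {
    expect_lt(abs(ft$estimates[[nm]] - truth[[nm]]),
              abs(x0[[nm]] - truth[[nm]]))
  }
})

test_that("noisy fits cover the truth and CIs widen with noise", {
  case <- default_case("case3")
  widths <- c()
  for (sd in c(0.05, 0.10)) {
    d <- generate_case_dataset(case, noise = noise_model(sd, 0, 99))
    ft <- fit_parameters(d, case, c("km", "km2", "alpha"),
                         x0 = c(km = 0.38, km2 = 0.38, alpha = 0.42),
                         control = list(maxit = 40), rtol = 1e-6,
                         atol = 1e-9)
    td <- tidy(ft)
    covered <- sum(td$conf.low <= c(0.54, 0.54, 0.6) &
                     td$conf.high >= c(0.54, 0.54, 0.6))
    expect_gte(covered, 2)
    widths <- c(widths, td$conf.high[td$term == "km"] -
                  td$conf.low[td$term == "km"])
  }
  expect_gt(widths[2], widths[1])
})

test_that("confidence intervals match the closed-form linear t-interval", {
  set.seed(5)
  x <- seq(0.1, 2, length.out = 25)
  y <- 1.7 * x + stats::rnorm(25, sd = 0.3)
  # residual function of the straight-line model through the origin
  est <- sum(x * y) / sum(x * x)
  r <- est * x - y
  ci <- confidence_intervals(c(theta = est), matrix(x, ncol = 1), r,
                             df = 24)
  lmfit <- lm(y ~ x - 1)
  expect_equal(ci$estimate, unname(coef(lmfit)), tolerance = 1e-10)
  ref <- unname(confint(lmfit, level = 0.95))
  expect_equal(c(ci$ci_low, ci$ci_high), c(ref[1], ref[2]),
               tolerance = 1e-10)
  # zero residuals give zero-width intervals
  ci0 <- confidence_intervals(c(theta = 2), matrix(x, ncol = 1),
                              rep(0, 25), df = 24)
  expect_equal(ci0$ci_low, ci0$ci_high)
})

test_that("rank-deficient problems are flagged unidentifiable", {
  # two parameters entering only through their sum: J has identical columns
  x <- seq(0, 1, length.out = 10)
  J <- cbind(x, x)
  ci <- confidence_intervals(c(a = 1, b = 2), J, rep(0.1, 10), df = 8)
  expect_false(any(ci$identifiable))
  expect_true(all(is.na(ci$std_error)))
  expect_error(confidence_intervals(c(a = 1), matrix(x), rep(0, 10), 0),
               "degrees of freedom")
})

test_that("fit report flags free vs fixed parameters", {
  case <- default_case("case1")
  d <- generate_case_dataset(case, interval = 4, t_end = 40,
                             noise = noise_model(0, 0, NULL))
  ft <- fit_parameters(d, case, "km", x0 = c(km = 2.0))
  rep_ <- fit_report(ft)
  expect_true(rep_$free[rep_$parameter == "km"])
  expect_false(any(rep_$free[rep_$parameter != "km"]))
  expect_true(all(is.na(rep_$ci_low[!rep_$free])))
})
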