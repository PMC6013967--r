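# Kinetic rate laws, stoichiometry, acid-base speciation and gas transfer.
# rhs() here is the readable R reference of the model right-hand side; the
# integrator uses an equivalent compiled version (they are cross-checked in
# the test suite).

check_rate_args <- function(args) {
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop_domain(nm, "must be a finite numeric scalar")
    if (v < 0) stop_domain(nm, "must be non-negative")
  }
}

#' Monod uptake rate
#'
#' Saturable specific uptake `km * E_factor * S / (S + Ks) * X * weight`
#' (cmol/L/h).  `E_factor` is 1 for phase-I rates and equals the E2 level
#' for the induced phase-II glucose rate; `weight` is the cybernetic
#' activity weight v.
#'
#' @param km maximal uptake rate, h^-1.
#' @param S substrate concentration, cmol/L.
#' @param Ks affinity constant, cmol/L (> 0).
#' @param X biomass, cmol/L.
#' @param weight cybernetic weight in `[0, 1]`.
#' @param E_factor enzyme-level multiplier (dimensionless, 1 for phase I).
#' @return Uptake rate, cmol/L/h.
#' @export
#' @examples
#' monod_uptake_rate(0.54, S = 0.1, Ks = 2e-4, X = 0.0016)
monod_uptake_rate <- function(km, S, Ks, X, weight = 1, E_factor = 1) {
  check_rate_args(list(km = km, S = S, Ks = Ks, X = X, weight = weight,
                       E_factor = E_factor))
  if (Ks <= 0) stop_domain("Ks", "must be strictly positive")
  km * E_factor * S / (S + Ks) * X * weight
}

#' Hill-kinetics enzyme synthesis rate
#'
#' Sigmoidal induction of the E2 uptake system by glucose:
#' `alpha * Glu^n / (Glu^n + Ks_E2^n) * X * u`, with `u` the cybernetic
#' allocation weight.
#'
#' @param alpha enzyme synthesis rate, h^-1.
#' @param Glu glucose concentration, cmol/L.
#' @param Ks_E2 induction affinity constant, cmol/L (> 0).
#' @param n Hill coefficient.
#' @param X biomass, cmol/L.
#' @param u cybernetic synthesis-allocation weight in `[0, 1]`.
#' @return Synthesis rate, cmol/L/h.
#' @export
hill_synthesis_rate <- function(alpha, Glu, Ks_E2, n, X, u = 1) {
  check_rate_args(list(alpha = alpha, Glu = Glu, Ks_E2 = Ks_E2, n = n,
                       X = X, u = u))
  if (Ks_E2 <= 0) stop_domain("Ks_E2", "must be strictly positive")
  alpha * Glu^n / (Glu^n + Ks_E2^n) * X * u
}

#' Cybernetic control weights
#'
#' Matching-law weights computed from the weight-free kinetic rates of the
#' two competing uptake routes (xylose via the constitutive system, glucose
#' via E2): `v1 = a / max(a, b)`, `v2 = b / max(a, b)`,
#' `u = b / (a + b)`.  The degenerate all-zero case returns
#' `v1 = v2 = 1, u = 0` (all rate products are zero anyway).
#'
#' @param rho_xyl_kinetic weight-free kinetic xylose uptake rate, cmol/L/h.
#' @param rho_glu2_kinetic weight-free kinetic phase-II glucose rate
#'   (including the E2 factor), cmol/L/h.
#' @return Named list with `v1`, `v2`, `u`, all in `[0, 1]`.
#' @export
#' @examples
#' cybernetic_weights(2, 1)
cybernetic_weights <- function(rho_xyl_kinetic, rho_glu2_kinetic) {
  check_rate_args(list(rho_xyl_kinetic = rho_xyl_kinetic,
                       rho_glu2_kinetic = rho_glu2_kinetic))
  a <- rho_xyl_kinetic
  b <- rho_glu2_kinetic
  m <- max(a, b)
  if (m == 0) return(list(v1 = 1, v2 = 1, u = 0))
  list(v1 = a / m, v2 = b / m, u = b / (a + b))
}

#' Net carbonate acid-base rate
#'
#' Rate of interconversion between dissolved CO2 and its ionic species
#' (bicarbonate + carbonate) at fixed pH:
#' `k_AB * (CO2aq * (10^(pH - pK1) + 10^(2 pH - pK1 - pK2)) - CO2sol)`.
#' Positive values convert CO2(aq) into ionic species.
#'
#' @param co2_aq dissolved CO2, cmol/L.
#' @param co2_sol bicarbonate + carbonate, cmol/L.
#' @param constants a [reactor_constants()].
#' @return Signed rate, cmol/L/h; exactly zero at the speciation
#'   equilibrium.
#' @export
acid_base_rate <- function(co2_aq, co2_sol, constants = reactor_constants()) {
  check_rate_args(list(co2_aq = co2_aq, co2_sol = co2_sol))
  frac <- carbonate_ratio(constants)
  constants$k_AB * (co2_aq * frac - co2_sol)
}

# equilibrium ratio CO2sol / CO2aq at the reactor pH
carbonate_ratio <- function(constants) {
  10^(constants$pH - constants$pK1) +
    10^(2 * constants$pH - constants$pK1 - constants$pK2)
}

#' Headspace partial pressure
#'
#' Ideal-gas partial pressure of a headspace component,
#' `p = conc * R * T` (atm) converted to Pa.
#'
#' @param gas_conc headspace concentration, mol per L of gas.
#' @param constants a [reactor_constants()].
#' @return Partial pressure, Pa.
#' @export
partial_pressure <- function(gas_conc, constants = reactor_constants()) {
  check_rate_args(list(gas_conc = gas_conc))
  gas_conc * constants$R_gas * constants$T * 101325
}

#' Gas-liquid mass-transfer rate
#'
#' Two-film rate `kla * (c_aq - p_gas * KH)`; zero exactly at Henry
#' equilibrium.  Units follow `c_aq` (mol/L/h for H2, cmol/L/h for CO2).
#'
#' @param kla volumetric mass-transfer coefficient, h^-1.
#' @param c_aq dissolved concentration.
#' @param p_gas headspace partial pressure, Pa.
#' @param KH Henry's constant, mol/L/Pa.
#' @return Signed transfer rate (positive = liquid to gas).
#' @export
gas_transfer_rate <- function(kla, c_aq, p_gas, KH) {
  check_rate_args(list(kla = kla))
  kla * (c_aq - p_gas * KH)
}

#' CO2 mass-transfer coefficient from the sparging rate
#'
#' Empirical power law `5.85 * (N2 / 6)^0.46` anchoring kLa(CO2) to the
#' nitrogen stripping rate (5.85 h^-1 at the reference 6 L/h).
#'
#' @param N2_sparge nitrogen sparging rate, L/h.
#' @return kLa for CO2, h^-1.
#' @export
#' @examples
#' kla_co2_from_sparging(6)
kla_co2_from_sparging <- function(N2_sparge) {
  check_rate_args(list(N2_sparge = N2_sparge))
  5.85 * (N2_sparge / 6)^0.46
}

#' Stoichiometric (catabolic) yields
#'
#' Yields of the acetate-producing catabolic reaction
#' `CH2O + 1/3 H2O -> 2/3 CH2O(acetate) + 1/3 CO2 + 2/3 H2` on a cmol
#' basis: Y_ac = 2/3 cmol/cmol, Y_h2 = 2/3 mol/cmol, Y_co2 = 1/3 cmol/cmol,
#' i.e. the classical 4 mol H2 per mol hexose ceiling (6 cmol * 2/3).
#'
#' @return A [yield_set()] with `Y_x = 0`; attribute `h2_per_hexose` gives
#'   the maximal molar H2 yield per mol hexose.
#' @export
#' @examples
#' attr(stoichiometric_yields(), "h2_per_hexose")
stoichiometric_yields <- function() {
  ys <- yield_set(Y_x = 0, Y_ac = 2 / 3, Y_h2 = 2 / 3, Y_co2 = 1 / 3)
  attr(ys, "h2_per_hexose") <- 6 * ys$Y_h2
  ys
}

#' Competitive inhibition factor and apparent affinity constant
#'
#' `I = 1 + S_I / K_I`; an apparent affinity constant under competitive
#' inhibition is `Ks_real * I`.  Used to interpret the elevated glucose
#' affinity constant observed in industrial hydrolysate medium.
#'
#' @param S_I inhibitor concentration, cmol/L.
#' @param K_I inhibition constant, cmol/L (> 0).
#' @return `competitive_inhibition_factor()`: dimensionless factor >= 1.
#' @export
competitive_inhibition_factor <- function(S_I, K_I) {
  check_rate_args(list(S_I = S_I))
  if (!is.numeric(K_I) || length(K_I) != 1 || !is.finite(K_I) || K_I <= 0)
    stop_domain("K_I", "must be strictly positive")
  1 + S_I / K_I
}

#' @rdname competitive_inhibition_factor
#' @param Ks_real intrinsic affinity constant, cmol/L.
#' @param I inhibition factor from [competitive_inhibition_factor()].
#' @return `apparent_Ks()`: apparent affinity constant, cmol/L.
#' @export
apparent_Ks <- function(Ks_real, I) {
  check_rate_args(list(Ks_real = Ks_real, I = I))
  if (I < 1) stop_domain("I", "inhibition factor must be >= 1")
  Ks_real * I
}

#' Model right-hand side
#'
#' Assembles the full derivative vector of the batch fermentation model:
#' Monod uptake of the three sugars (phase I), E2-mediated phase-II glucose
#' uptake under cybernetic control, biomass growth and first-order death,
#' acetate/H2/CO2 formation, carbonate speciation, gas-liquid transfer and
#' headspace washout.  Three cumulative bookkeeping pools (washed-out H2
#' and CO2, decayed biomass) are carried along so that mass balances close
#' exactly.
#'
#' @param t time, h (the system is autonomous; kept for the usual solver
#'   signature).
#' @param state an [model_state()] or named vector; optionally extended
#'   with `h2out`, `co2out`, `xdead` bookkeeping pools.
#' @param case an [case_definition()].
#' @param constants a [reactor_constants()].
#' @param q_gas_mode `"n2_plus_product"` (headspace outflow = sparge +
#'   product gas, floored at the sparge rate) or `"n2_only"`.
#' @return List with `dydt` (named derivative vector over the 11 states +
#'   3 pools), the rate vector `rates`, cybernetic weights and `q_gas`.
#' @export
rhs <- function(t, state, case, constants = reactor_constants(),
                q_gas_mode = c("n2_plus_product", "n2_only")) {
  q_gas_mode <- match.arg(q_gas_mode)
  if (any(!is.finite(state)))
    stop(sprintf("non-finite state at t = %g h", t), call. = FALSE)
  s <- pmax(as.numeric(state[STATE_VARS]), 0)
  names(s) <- STATE_VARS
  pools <- setNames(numeric(3), names(AUX_COLS))
  p <- case$parameters
  y <- case$yields

  rho_xyl_kin <- monod_uptake_rate(p$km, s[["xyl"]], p$Ks_xyl, s[["x"]])
  rho_glu2_kin <- if (case$diauxic_enabled)
    monod_uptake_rate(p$km2, s[["glu"]], p$Ks_glu2, s[["x"]],
                      E_factor = s[["e2"]]) else 0
  w <- if (case$diauxic_enabled)
    cybernetic_weights(rho_xyl_kin, rho_glu2_kin)
  else list(v1 = 1, v2 = 0, u = 0)

  rho_glu <- monod_uptake_rate(p$km, s[["glu"]], p$Ks_glu, s[["x"]],
                               weight = w$v1)
  rho_xyl <- rho_xyl_kin * w$v1
  rho_ara <- monod_uptake_rate(p$km, s[["ara"]], p$Ks_ara, s[["x"]],
                               weight = w$v1)
  rho_glu2 <- rho_glu2_kin * w$v2
  rho_E <- if (case$diauxic_enabled)
    hill_synthesis_rate(p$alpha, s[["glu"]], p$Ks_E2, p$n_hill, s[["x"]],
                        u = w$u) else 0
  sum_rho <- rho_glu + rho_glu2 + rho_xyl + rho_ara

  rho_ab <- acid_base_rate(s[["co2aq"]], s[["co2sol"]], constants)
  p_h2 <- partial_pressure(s[["h2g"]], constants)
  p_co2 <- partial_pressure(s[["co2g"]], constants)
  rho_t_h2 <- gas_transfer_rate(p$kla_h2, s[["h2aq"]], p_h2,
                                constants$KH_h2)
  rho_t_co2 <- gas_transfer_rate(constants$kla_co2, s[["co2aq"]], p_co2,
                                 constants$KH_co2)

  q_gas <- constants$N2_sparge
  if (q_gas_mode == "n2_plus_product") {
    prod <- constants$V_liq * (rho_t_h2 + rho_t_co2) * constants$R_gas *
      constants$T
    q_gas <- q_gas + max(0, prod)
  }

  om <- 1 - y$Y_x
  d <- c(
    glu = -rho_glu - rho_glu2,
    xyl = -rho_xyl,
    ara = -rho_ara,
    x = y$Y_x * sum_rho - p$r_cd * s[["x"]],
    ac = om * y$Y_ac * sum_rho,
    h2aq = om * y$Y_h2 * sum_rho - rho_t_h2,
    co2aq = om * y$Y_co2 * sum_rho - rho_t_co2 - rho_ab,
    co2sol = rho_ab,
    h2g = constants$V_liq / constants$V_gas * rho_t_h2 -
      s[["h2g"]] * q_gas / constants$V_gas,
    co2g = constants$V_liq / constants$V_gas * rho_t_co2 -
      s[["co2g"]] * q_gas / constants$V_gas,
    e2 = if (case$diauxic_enabled)
      rho_E - p$beta * s[["e2"]] - s[["e2"]] * rho_glu2 else 0,
    h2out = q_gas * s[["h2g"]] / constants$V_liq,
    co2out = q_gas * s[["co2g"]] / constants$V_liq,
    xdead = p$r_cd * s[["x"]]
  )

  list(dydt = d,
       rates = c(rho_glu = rho_glu, rho_glu2 = rho_glu2, rho_xyl = rho_xyl,
                 rho_ara = rho_ara, rho_E = rho_E,
                 rho_dec_E2 = p$beta * s[["e2"]],
                 rho_dec_X = p$r_cd * s[["x"]], rho_AB_co2 = rho_ab,
                 rho_t_h2 = rho_t_h2, rho_t_co2 = rho_t_co2),
       weights = w, q_gas = q_gas)
}
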