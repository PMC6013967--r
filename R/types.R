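# Domain types: reactor constants, kinetic parameters, yields, model state,
# and case definitions.  All are plain named lists/vectors with validating
# constructors, so they print readably and serialise to YAML without fuss.


stop_domain <- function(name, msg) {
  stop(sprintf("invalid `%s`: %s", name, msg), call. = FALSE)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop_domain(name, "must be a finite numeric scalar")
  if (x < 0) stop_domain(name, "must be non-negative")
  invisible(x)
}

check_pos <- function(x, name) {
  check_nonneg(x, name)
  if (x <= 0) stop_domain(name, "must be strictly positive")
  invisible(x)
}

#' Reactor and physico-chemical constants
#'
#' Defaults describe the 1 L working-volume batch reactor the model was
#' built for: constant pH 6.5, 70 degC, 0.05 L headspace, nitrogen sparging
#' at 6 L/h, Henry solubilities for H2 and CO2, carbonate dissociation
#' constants, and an effectively instantaneous acid-base rate constant
#' (`k_AB = 1e4`), which is what makes the ODE system stiff.
#'
#' @param V_liq liquid (working) volume, L.
#' @param V_gas headspace volume, L.
#' @param pH culture pH (held constant by titration).
#' @param k_AB acid-base rate constant, h^-1 scale; large = near equilibrium.
#' @param T temperature, K.
#' @param R_gas ideal gas constant, L atm / K / mol.
#' @param KH_h2,KH_co2 Henry's constants, mol/L/Pa.
#' @param pK1,pK2 carbonate dissociation constants (bicarbonate, carbonate).
#' @param N2_sparge nitrogen stripping rate, L/h.
#' @return An object of class `fh2_constants` (named list).  The CO2
#'   volumetric mass-transfer coefficient `kla_co2` is derived from the
#'   sparging rate via [kla_co2_from_sparging()].
#' @export
#' @examples
#' reactor_constants()
reactor_constants <- function(V_liq = 1, V_gas = 0.05, pH = 6.5,
                              k_AB = 1e4, T = 343.15, R_gas = 0.08206,
                              KH_h2 = 7.4e-9, KH_co2 = 2.7e-7,
                              pK1 = 6.3, pK2 = 10.25, N2_sparge = 6) {
  for (nm in c("V_liq", "V_gas", "T", "R_gas"))
    check_pos(get(nm), nm)
  check_nonneg(k_AB, "k_AB")
  check_nonneg(N2_sparge, "N2_sparge")
  check_pos(KH_h2, "KH_h2"); check_pos(KH_co2, "KH_co2")
  if (!(pK1 < pK2)) stop_domain("pK1", "must satisfy pK1 < pK2")
  out <- list(V_liq = V_liq, V_gas = V_gas, pH = pH, k_AB = k_AB, T = T,
              R_gas = R_gas, KH_h2 = KH_h2, KH_co2 = KH_co2, pK1 = pK1,
              pK2 = pK2, N2_sparge = N2_sparge,
              kla_co2 = kla_co2_from_sparging(N2_sparge))
  structure(out, class = "fh2_constants")
}

#' Kinetic parameters of the uptake / induction model
#'
#' Defaults are the values calibrated for the defined sugar-mixture
#' fermentation (Case 3).  `km` is the shared phase-I maximal specific
#' uptake rate of glucose, xylose and arabinose; `km2` the phase-II
#' glucose rate through the induced E2 system; `alpha`/`beta` govern E2
#' synthesis and decay; `n_hill` is the Hill cooperativity of E2 induction;
#' `r_cd` the first-order cell death rate; `kla_h2` the H2 gas-transfer
#' coefficient.
#'
#' @param km,km2 maximal uptake rates (h^-1) for phase I and phase II.
#' @param Ks_glu,Ks_glu2,Ks_xyl,Ks_ara substrate affinity constants, cmol/L.
#' @param Ks_E2 affinity constant of E2 synthesis, cmol/L.
#' @param alpha enzyme synthesis rate, h^-1.
#' @param beta enzyme decay rate, h^-1.
#' @param n_hill Hill coefficient (>= 1).
#' @param r_cd cell death rate, h^-1.
#' @param kla_h2 volumetric H2 mass-transfer coefficient, h^-1.
#' @return An object of class `fh2_parameters` (named list).
#' @export
#' @examples
#' kinetic_parameters(km = 0.44, km2 = 1.26)
kinetic_parameters <- function(km = 0.54, km2 = 0.54, Ks_glu = 0.01,
                               Ks_glu2 = 0.01, Ks_xyl = 2e-4,
                               Ks_ara = 0.026, Ks_E2 = 0.001, alpha = 0.6,
                               beta = 0.05, n_hill = 2, r_cd = 0.027,
                               kla_h2 = 0.44) {
  for (nm in c("km", "km2", "alpha", "beta", "r_cd", "kla_h2"))
    check_nonneg(get(nm), nm)
  for (nm in c("Ks_glu", "Ks_glu2", "Ks_xyl", "Ks_ara", "Ks_E2"))
    check_pos(get(nm), nm)
  check_nonneg(n_hill, "n_hill")
  if (n_hill < 1) stop_domain("n_hill", "Hill coefficient must be >= 1")
  structure(list(km = km, km2 = km2, Ks_glu = Ks_glu, Ks_glu2 = Ks_glu2,
                 Ks_xyl = Ks_xyl, Ks_ara = Ks_ara, Ks_E2 = Ks_E2,
                 alpha = alpha, beta = beta, n_hill = n_hill, r_cd = r_cd,
                 kla_h2 = kla_h2),
            class = "fh2_parameters")
}

#' Conversion yields from consumed sugar
#'
#' `Y_x` (biomass) and `Y_ac`, `Y_co2` are cmol product per cmol sugar;
#' `Y_h2` is mol H2 per cmol sugar.  The carbon balance of the catabolic
#' reaction closes exactly when `Y_ac + Y_co2 = 1`.
#'
#' @param Y_x biomass yield, cmol/cmol.
#' @param Y_ac acetate yield, cmol/cmol.
#' @param Y_h2 hydrogen yield, mol/cmol.
#' @param Y_co2 carbon dioxide yield, cmol/cmol.
#' @return An object of class `fh2_yields`; attribute `carbon_closed` is
#'   `TRUE` iff `Y_ac + Y_co2 == 1` within 1e-6.
#' @export
#' @examples
#' yield_set(0.21, 0.62, 0.53, 0.38)
yield_set <- function(Y_x, Y_ac, Y_h2, Y_co2) {
  for (nm in c("Y_x", "Y_ac", "Y_h2", "Y_co2")) {
    v <- check_nonneg(get(nm), nm)
    if (v > 1) stop_domain(nm, "yields must lie in [0, 1]")
  }
  structure(list(Y_x = Y_x, Y_ac = Y_ac, Y_h2 = Y_h2, Y_co2 = Y_co2),
            carbon_closed = abs(Y_ac + Y_co2 - 1) < 1e-6,
            class = "fh2_yields")
}

#' Model state vector
#'
#' The eleven dynamic states: sugars, biomass
#' (CH1.62O0.46N0.23S0.0052P0.0071), acetate (all cmol/L), dissolved and
#' headspace H2 (mol/L), dissolved/ionic/headspace CO2 (cmol/L) and the
#' inducible uptake system E2 (cmol/L).
#'
#' @param glu,xyl,ara sugar concentrations, cmol/L.
#' @param x biomass, cmol/L.
#' @param ac acetate, cmol/L.
#' @param h2aq dissolved hydrogen, mol/L.
#' @param co2aq dissolved carbon dioxide, cmol/L.
#' @param co2sol bicarbonate + carbonate, cmol/L.
#' @param h2g headspace hydrogen, mol per L of gas.
#' @param co2g headspace carbon dioxide, cmol per L of gas.
#' @param e2 inducible enzyme system E2, cmol/L.
#' @return Named numeric vector of length 11, class `fh2_state`.
#' @export
#' @examples
#' model_state(glu = 0.28, xyl = 0.10, ara = 0.012, x = 0.0016, e2 = 1e-7)
model_state <- function(glu = 0, xyl = 0, ara = 0, x = 0, ac = 0, h2aq = 0,
                        co2aq = 0, co2sol = 0, h2g = 0, co2g = 0, e2 = 0) {
  vals <- c(glu = glu, xyl = xyl, ara = ara, x = x, ac = ac, h2aq = h2aq,
            co2aq = co2aq, co2sol = co2sol, h2g = h2g, co2g = co2g,
            e2 = e2)
  for (nm in names(vals)) check_nonneg(unname(vals[[nm]]), nm)
  structure(vals, class = "fh2_state")
}

#' Define a fermentation case
#'
#' Bundles initial state, kinetic parameters, yields and horizon.  When
#' `diauxic_enabled = FALSE` the phase-II machinery is switched off: E2 is
#' frozen at zero, the second glucose uptake rate and enzyme synthesis are
#' zero and the cybernetic weight v1 is 1 throughout, i.e. a plain
#' multi-substrate Monod model.
#'
#' @param name case label.
#' @param initial_state an [model_state()].
#' @param parameters a [kinetic_parameters()].
#' @param yields a [yield_set()].
#' @param diauxic_enabled logical; activate E2 induction / cybernetic
#'   switching.
#' @param t_end simulation horizon, h.
#' @return An object of class `fh2_case`.
#' @export
case_definition <- function(name, initial_state, parameters, yields,
                            diauxic_enabled = TRUE, t_end = 80) {
  stopifnot(inherits(initial_state, "fh2_state"),
            inherits(parameters, "fh2_parameters"),
            inherits(yields, "fh2_yields"))
  check_pos(t_end, "t_end")
  if (!diauxic_enabled) initial_state[["e2"]] <- 0
  structure(list(name = as.character(name), initial_state = initial_state,
                 parameters = parameters, yields = yields,
                 diauxic_enabled = isTRUE(diauxic_enabled), t_end = t_end),
            class = "fh2_case")
}

#' @export
print.fh2_case <- function(x, ...) {
  cat("<fh2_case> ", x$name,
      if (x$diauxic_enabled) " (diauxic phase II enabled)" else
        " (phase I only)", "\n", sep = "")
  st <- x$initial_state
  nz <- st[st > 0]
  cat("  t_end: ", x$t_end, " h;  nonzero initial states: ",
      paste(sprintf("%s=%g", names(nz), nz), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.fh2_constants <- function(x, ...) {
  cat("<fh2_constants>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' @export
print.fh2_parameters <- function(x, ...) {
  cat("<fh2_parameters>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

# flatten helpers used by the solver bridge ---------------------------------

kin_vector <- function(parameters, yields) {
  c(unlist(parameters[KIN_PARS], use.names = FALSE),
    unlist(yields[c("Y_x", "Y_ac", "Y_h2", "Y_co2")], use.names = FALSE))
}

cons_vector <- function(constants) {
  unlist(constants[c("V_liq", "V_gas", "pH", "k_AB", "T", "R_gas", "KH_h2",
                     "KH_co2", "pK1", "pK2", "N2_sparge", "kla_co2")],
         use.names = FALSE)
}
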