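# Data-derived quantities: unit conversions, yield slopes and corrections,
# maximal specific growth rates, lag-phase detection and the full yield
# pipeline on a trajectory.

# molar masses (g/mol) and carbon atoms per molecule
SPECIES_TABLE <- list(
  glucose   = c(mw = 180.16, nC = 6),
  xylose    = c(mw = 150.13, nC = 5),
  arabinose = c(mw = 150.13, nC = 5),
  acetate   = c(mw = 60.05,  nC = 2),
  # CH1.62 O0.46 N0.23 S0.0052 P0.0071, per cmol
  biomass   = c(mw = 24.62,  nC = 1)
)

species_entry <- function(species) {
  if (!is.character(species) || length(species) != 1 ||
      !species %in% names(SPECIES_TABLE))
    stop(sprintf("unknown species '%s'; known: %s", species,
                 paste(names(SPECIES_TABLE), collapse = ", ")),
         call. = FALSE)
  SPECIES_TABLE[[species]]
}

#' Convert between mass and carbon-mole concentrations
#'
#' `mass_to_cmol()` converts g/L to cmol/L (`conc / MW * carbons`);
#' `cmol_to_mass()` is its exact inverse.  Known species: glucose, xylose,
#' arabinose, acetate and biomass (24.62 g per cmol from the elemental
#' formula CH1.62O0.46N0.23S0.0052P0.0071).
#'
#' @param conc_g_L concentration in g/L (vectorised).
#' @param species species name.
#' @return Concentration in cmol/L.
#' @export
#' @examples
#' mass_to_cmol(12.11, "glucose")
mass_to_cmol <- function(conc_g_L, species) {
  sp <- species_entry(species)
  if (any(!is.finite(conc_g_L)) || any(conc_g_L < 0))
    stop_domain("conc_g_L", "must be finite and non-negative")
  conc_g_L / sp[["mw"]] * sp[["nC"]]
}

#' @rdname mass_to_cmol
#' @param conc_cmol_L concentration in cmol/L.
#' @export
cmol_to_mass <- function(conc_cmol_L, species) {
  sp <- species_entry(species)
  if (any(!is.finite(conc_cmol_L)) || any(conc_cmol_L < 0))
    stop_domain("conc_cmol_L", "must be finite and non-negative")
  conc_cmol_L * sp[["mw"]] / sp[["nC"]]
}

#' Ordinary least-squares yield slope
#'
#' Slope of product (or biomass) against consumed total sugar, both in
#' cmol/L, over an optional phase mask.  This is the raw "curve slope"
#' that [corrected_yield()] turns into a true yield.
#'
#' @param x consumed total sugar, cmol/L.
#' @param y product or biomass, cmol/L.
#' @param phase_mask logical vector selecting the points to use (e.g. the
#'   phase-I mask); default all.
#' @return A tibble with `slope`, `stderr` and `n`.
#' @export
fit_yield_slope <- function(x, y, phase_mask = NULL) {
  if (is.null(phase_mask)) phase_mask <- rep(TRUE, length(x))
  stopifnot(length(x) == length(y), length(phase_mask) == length(x))
  x <- x[phase_mask]
  y <- y[phase_mask]
  if (length(x) < 3)
    stop("need at least 3 points to fit a yield slope", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate fit: consumed sugar does not vary", call. = FALSE)
  fit <- lm(y ~ x)
  # suppress the spurious "essentially perfect fit" warning on noiseless
  # round-trip data
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(slope = sm["x", "Estimate"],
                 stderr = sm["x", "Std. Error"], n = length(x))
}

#' Correct a product slope for carbon diverted to biomass
#'
#' True product yield from the raw slope: `slope / (1 - Y_x)`, because only
#' the fraction `(1 - Y_x)` of consumed sugar enters catabolism.
#'
#' @param slope raw slope of product vs consumed sugar, cmol/cmol.
#' @param Y_x biomass yield in `[0, 1)`.
#' @return Corrected yield, cmol/cmol.
#' @export
#' @examples
#' corrected_yield(0.49, 0.21)
corrected_yield <- function(slope, Y_x) {
  if (!is.finite(Y_x) || Y_x < 0 || Y_x >= 1)
    stop_domain("Y_x", "must lie in [0, 1)")
  slope / (1 - Y_x)
}

#' Hydrogen yield from endpoint totals
#'
#' `(H2_end - H2_start) / (sugar_start - sugar_end)` in mol H2 per cmol
#' sugar, where the H2 totals must account for liquid-to-gas transport
#' (dissolved + headspace + washed-out hydrogen).
#'
#' @param h2_start,h2_end total accumulated hydrogen, mol per L liquid.
#' @param sugar_start,sugar_end total sugar, cmol/L.
#' @return Yield, mol/cmol.
#' @export
h2_yield <- function(h2_start, h2_end, sugar_start, sugar_end) {
  if (!(sugar_start > sugar_end))
    stop("zero or negative sugar consumption: hydrogen yield undefined",
         call. = FALSE)
  (h2_end - h2_start) / (sugar_start - sugar_end)
}

#' Maximal specific growth rate from uptake kinetics
#'
#' `mu_max = n_sugars * km * Y_x`: at saturating substrate each of the
#' `n_sugars` co-consumed sugars contributes its maximal specific uptake
#' rate, and the biomass yield converts uptake into growth.  Use
#' `n_sugars = 3` for phase I of the mixture cases and 1 for phase II or
#' single-sugar growth.
#'
#' @param km_effective maximal uptake rate of the phase, h^-1.
#' @param Y_x biomass yield, cmol/cmol.
#' @param n_sugars number of co-consumed sugars.
#' @return mu_max, h^-1.
#' @export
#' @examples
#' mu_max(1.26, 0.18, 1)
mu_max <- function(km_effective, Y_x, n_sugars = 1) {
  check_pos(km_effective, "km_effective")
  check_pos(Y_x, "Y_x")
  check_pos(n_sugars, "n_sugars")
  n_sugars * km_effective * Y_x
}

#' Detect the lag phase of a batch culture
#'
#' Intersects a horizontal line through the initial plateau of `ln X`
#' (the minimum of the first `plateau_n` values, so a lag-free
#' exponential yields zero) with a straight-line fit to the steepest
#' `window`-point segment of `ln X`
#' (the exponential phase); the abscissa of the intersection, floored at
#' zero, is the lag duration.
#'
#' @param t time, h.
#' @param X biomass, cmol/L (strictly positive).
#' @param plateau_n number of initial points defining the plateau.
#' @param window sliding-window width for the exponential segment.
#' @param min_slope minimal specific growth rate (h^-1) for a segment to
#'   count as exponential; below it the function warns and returns 0.
#' @return Lag duration, h.
#' @export
detect_lag <- function(t, X, plateau_n = 3, window = 5, min_slope = 0.01) {
  stopifnot(length(t) == length(X))
  if (length(t) < max(6, window + 1))
    stop("need at least 6 points to detect a lag phase", call. = FALSE)
  if (any(X <= 0))
    stop("biomass must be strictly positive to take logarithms",
         call. = FALSE)
  lx <- log(X)
  # plateau level: minimum of the first points, so a lag-free exponential
  # intersects at t = 0 instead of at the plateau-window midpoint
  plateau <- min(lx[seq_len(plateau_n)])
  n <- length(t)
  best <- list(slope = -Inf)
  for (i in seq_len(n - window + 1)) {
    idx <- i:(i + window - 1)
    cf <- coef(lm(lx[idx] ~ t[idx]))
    if (cf[2] > best$slope)
      best <- list(slope = unname(cf[2]), intercept = unname(cf[1]))
  }
  if (best$slope < min_slope) {
    warning("no exponential segment detected; returning lag = 0")
    return(0)
  }
  max(0, (plateau - best$intercept) / best$slope)
}

#' Phase-I mask of a trajectory
#'
#' Time points at which xylose is still above `threshold` times its
#' initial value; when the trajectory starts without xylose all points are
#' phase I.
#'
#' @param series a trajectory tibble with `xyl_cmol_L`.
#' @param threshold fraction of initial xylose below which phase I ends.
#' @return Logical vector.
#' @export
phase1_mask <- function(series, threshold = 0.01) {
  xyl0 <- series$xyl_cmol_L[1]
  if (xyl0 <= 0) return(rep(TRUE, nrow(series)))
  series$xyl_cmol_L > threshold * xyl0
}

#' Estimate all conversion yields from a trajectory
#'
#' Applies the full data-analysis pipeline to a (simulated or measured)
#' batch trajectory: biomass yield from the phase-I slope of biomass vs
#' consumed sugar, acetate and CO2 yields from their slopes corrected by
#' `1/(1 - Y_x)`, and the hydrogen yield from the endpoint totals of
#' accumulated hydrogen (dissolved + headspace + washed out).  With
#' `decay_correction = TRUE` the biomass lost to first-order death
#' (`r_cd * integral of X dt`, trapezoidal) is added back before the
#' slopes are taken, which removes the downward bias the death term
#' introduces.
#'
#' @param series a trajectory tibble (e.g. from [simulate_batch()] or
#'   [generate_case_dataset()]); must include the CO2 pool columns and
#'   `h2acc_mol_L` for the CO2 and H2 yields.
#' @param constants a [reactor_constants()]; defaults to the stored
#'   attribute.
#' @param r_cd cell death rate used for the decay correction; defaults to
#'   the value in the `case` attribute of `series`, else 0.
#' @param decay_correction logical.
#' @param phase_threshold passed to [phase1_mask()].
#' @return A tibble with one row per yield (`Y_x`, `Y_ac`, `Y_co2`,
#'   `Y_h2`): `estimate`, `slope`, `stderr`, `phase`.
#' @export
estimate_yields <- function(series, constants = NULL, r_cd = NULL,
                            decay_correction = TRUE,
                            phase_threshold = 0.01) {
  cs <- sim_constants(series, constants)
  if (is.null(r_cd)) {
    case <- attr(series, "case")
    r_cd <- if (!is.null(case)) case$parameters$r_cd else 0
  }
  tot_sugar <- series$glu_cmol_L + series$xyl_cmol_L + series$ara_cmol_L
  consumed <- tot_sugar[1] - tot_sugar
  X <- series$x_cmol_L
  if (decay_correction && r_cd > 0)
    X <- X + r_cd * cumtrapz(series$time_h, X)

  mask1 <- phase1_mask(series, phase_threshold)
  yx <- fit_yield_slope(consumed, X, mask1)
  Y_x <- yx$slope

  ac_fit <- fit_yield_slope(consumed, series$ac_cmol_L)
  Y_ac <- corrected_yield(ac_fit$slope, Y_x)

  vr <- cs$V_gas / cs$V_liq
  co2_tot <- series$co2aq_cmol_L + series$co2sol_cmol_L +
    vr * series$co2g_cmol_L +
    (if ("co2w_cmol_L" %in% names(series)) series$co2w_cmol_L else 0)
  co2_fit <- fit_yield_slope(consumed, co2_tot)
  Y_co2 <- corrected_yield(co2_fit$slope, Y_x)

  if (!"h2acc_mol_L" %in% names(series))
    stop("series lacks `h2acc_mol_L`; cannot account for washed-out H2",
         call. = FALSE)
  h2_tot <- series$h2acc_mol_L + series$h2aq_M + vr * series$h2g_M
  n <- nrow(series)
  Y_h2raw <- h2_yield(h2_tot[1], h2_tot[n], tot_sugar[1], tot_sugar[n])
  Y_h2 <- corrected_yield(Y_h2raw, Y_x)

  tibble::tibble(
    yield = c("Y_x", "Y_ac", "Y_co2", "Y_h2"),
    estimate = c(Y_x, Y_ac, Y_co2, Y_h2),
    slope = c(yx$slope, ac_fit$slope, co2_fit$slope, Y_h2raw),
    stderr = c(yx$stderr, ac_fit$stderr, co2_fit$stderr, NA_real_),
    phase = c("I", "all", "all", "endpoints"))
}
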