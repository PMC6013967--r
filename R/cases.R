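# The four canonical fermentation cases with their published start values,
# calibrated kinetic parameters and data-derived yields.

#' Built-in fermentation cases
#'
#' Returns the four batch fermentation cases the model was developed on,
#' preloaded with their measured start values (cmol basis), calibrated
#' kinetic parameters and conversion yields:
#'
#' * `case1` - 10 g/L glucose, defined medium (phase I only);
#' * `case2` - 10 g/L xylose, defined medium (phase I only);
#' * `case3` - defined glucose/xylose/arabinose mixture (diauxic model);
#' * `case4` - wheat straw hydrolysate, ~10 g/L total sugar (diauxic
#'   model).
#'
#' The single-sugar cases are simulated without the phase-II machinery
#' (no E2 induction, v1 = 1).  For `case1` the single calibrated glucose
#' uptake rate (2.4 h^-1, reported as the "xylose = 0" rate) acts as the
#' phase-I `km`.
#'
#' @return `default_case_library()`: named list of [case_definition()]s.
#' @export
#' @examples
#' names(default_case_library())
#' default_case("case3")
default_case_library <- function() {
  list(
    case1 = case_definition(
      name = "case1",
      initial_state = model_state(glu = 0.40, x = 0.0013, ac = 0.0012),
      parameters = kinetic_parameters(
        km = 2.4, km2 = 0, Ks_glu = 0.01, r_cd = 0.0027, kla_h2 = 0.44,
        alpha = 0),
      yields = yield_set(Y_x = 0.20, Y_ac = 0.51, Y_h2 = 0.45,
                         Y_co2 = 0.30),
      diauxic_enabled = FALSE),
    case2 = case_definition(
      name = "case2",
      initial_state = model_state(xyl = 0.36, x = 0.00071),
      parameters = kinetic_parameters(
        km = 1.58, km2 = 0, Ks_xyl = 2e-4, r_cd = 0.0027, kla_h2 = 0.44,
        alpha = 0),
      yields = yield_set(Y_x = 0.12, Y_ac = 0.50, Y_h2 = 0.47,
                         Y_co2 = 0.31),
      diauxic_enabled = FALSE),
    case3 = case_definition(
      name = "case3",
      initial_state = model_state(glu = 0.28, xyl = 0.10, ara = 0.012,
                                  x = 0.0016, ac = 0.0039, e2 = 1e-7),
      parameters = kinetic_parameters(
        km = 0.54, km2 = 0.54, Ks_glu = 0.01, Ks_glu2 = 0.01,
        Ks_xyl = 2e-4, Ks_ara = 0.026, Ks_E2 = 0.001, alpha = 0.6,
        n_hill = 2, r_cd = 0.027, kla_h2 = 0.44),
      yields = yield_set(Y_x = 0.21, Y_ac = 0.62, Y_h2 = 0.53,
                         Y_co2 = 0.38),
      diauxic_enabled = TRUE),
    case4 = case_definition(
      name = "case4",
      initial_state = model_state(glu = 0.26, xyl = 0.11, ara = 0.014,
                                  x = 0.0058, ac = 0.021, e2 = 1e-7),
      parameters = kinetic_parameters(
        km = 0.44, km2 = 1.26, Ks_glu = 0.18, Ks_glu2 = 0.01,
        Ks_xyl = 2e-4, Ks_ara = 0.034, Ks_E2 = 0.001, alpha = 0.64,
        n_hill = 2, r_cd = 0.027, kla_h2 = 0.44),
      yields = yield_set(Y_x = 0.18, Y_ac = 0.68, Y_h2 = 0.67,
                         Y_co2 = 0.44),
      diauxic_enabled = TRUE)
  )
}

#' @rdname default_case_library
#' @param name one of `"case1"` ... `"case4"`.
#' @return `default_case()`: a single [case_definition()].
#' @export
default_case <- function(name) {
  lib <- default_case_library()
  if (!name %in% names(lib))
    stop(sprintf("unknown case '%s'; available: %s", name,
                 paste(names(lib), collapse = ", ")), call. = FALSE)
  lib[[name]]
}
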