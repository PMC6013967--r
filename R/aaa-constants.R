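# Shared name tables: state variables, tibble/CSV column names, kinetic
# parameter names.

STATE_VARS <- c("glu", "xyl", "ara", "x", "ac", "h2aq", "co2aq", "co2sol",
                "h2g", "co2g", "e2")

# column names used in tibbles / CSV (units encoded to avoid cmol-vs-g mixups)
STATE_COLS <- c(
  glu = "glu_cmol_L", xyl = "xyl_cmol_L", ara = "ara_cmol_L",
  x = "x_cmol_L", ac = "ac_cmol_L", h2aq = "h2aq_M",
  co2aq = "co2aq_cmol_L", co2sol = "co2sol_cmol_L", h2g = "h2g_M",
  co2g = "co2g_cmol_L", e2 = "e2_cmol_L"
)
AUX_COLS <- c(h2out = "h2acc_mol_L", co2out = "co2w_cmol_L",
              xdead = "xdead_cmol_L")

KIN_PARS <- c("km", "km2", "Ks_glu", "Ks_glu2", "Ks_xyl", "Ks_ara", "Ks_E2",
              "alpha", "beta", "n_hill", "r_cd", "kla_h2")

# default probe set and tracked states of the sensitivity analysis
SENS_PARAMS <- c("km", "km2", "Ks_glu", "Ks_glu2", "Ks_xyl", "Ks_ara",
                 "Ks_E2", "alpha", "n_hill", "r_cd", "kla_h2")
SENS_STATES <- c(glu = "glu_cmol_L", xyl = "xyl_cmol_L",
                 ara = "ara_cmol_L", ac = "ac_cmol_L", x = "x_cmol_L",
                 h2 = "h2acc_mol_L")
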