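// Stiff ODE core for the diauxic fermentation model.
//
// The acid-base rate constant k_AB = 1e4 h^-1 makes the system stiff
// (fastest mode ~1e-4 h against an 80 h horizon), so the integrator is a
// Rosenbrock one-step method of order 2(3) in the style of MATLAB's ode23s
// (Shampine & Reichelt 1997), L-stable and cheap per step for an
// 14-dimensional state.  The Jacobian is refreshed every step by forward
// differences.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NS = 14;
// state indices
enum {
  I_GLU = 0, I_XYL, I_ARA, I_X, I_AC, I_H2AQ, I_CO2AQ, I_CO2SOL,
  I_H2G, I_CO2G, I_E2, I_H2OUT, I_CO2OUT, I_XDEAD
};

struct Pars {
  // kinetic parameters + yields (kin vector, length 16)
  double km, km2, Ks_glu, Ks_glu2, Ks_xyl, Ks_ara, Ks_E2;
  double alpha, beta, n_hill, r_cd, kla_h2;
  double Y_x, Y_ac, Y_h2, Y_co2;
  // reactor constants (cons vector, length 12)
  double V_liq, V_gas, pH, k_AB, T, R_gas, KH_h2, KH_co2, pK1, pK2;
  double N2, kla_co2;
  bool diauxic;
  int qgas_mode; // 0 = n2_plus_product, 1 = n2_only
};

static Pars unpack(const NumericVector& kin, const NumericVector& cons,
                   bool diauxic, int qgas_mode) {
  Pars p;
  p.km = kin[0];  p.km2 = kin[1];  p.Ks_glu = kin[2]; p.Ks_glu2 = kin[3];
  p.Ks_xyl = kin[4]; p.Ks_ara = kin[5]; p.Ks_E2 = kin[6];
  p.alpha = kin[7]; p.beta = kin[8]; p.n_hill = kin[9];
  p.r_cd = kin[10]; p.kla_h2 = kin[11];
  p.Y_x = kin[12]; p.Y_ac = kin[13]; p.Y_h2 = kin[14]; p.Y_co2 = kin[15];
  p.V_liq = cons[0]; p.V_gas = cons[1]; p.pH = cons[2]; p.k_AB = cons[3];
  p.T = cons[4]; p.R_gas = cons[5]; p.KH_h2 = cons[6]; p.KH_co2 = cons[7];
  p.pK1 = cons[8]; p.pK2 = cons[9]; p.N2 = cons[10]; p.kla_co2 = cons[11];
  p.diauxic = diauxic;
  p.qgas_mode = qgas_mode;
  return p;
}

static inline double clip0(double x) { return x > 0.0 ? x : 0.0; }

// Right-hand side.  States are clipped at zero for rate evaluation so that
// small negative solver excursions never yield negative rates.
static void rhs(const arma::vec& y, const Pars& p, arma::vec& dy,
                double* qgas_out) {
  const double glu = clip0(y[I_GLU]), xyl = clip0(y[I_XYL]),
               ara = clip0(y[I_ARA]), X = clip0(y[I_X]),
               h2aq = clip0(y[I_H2AQ]), co2aq = clip0(y[I_CO2AQ]),
               co2sol = clip0(y[I_CO2SOL]), h2g = clip0(y[I_H2G]),
               co2g = clip0(y[I_CO2G]), e2 = clip0(y[I_E2]);

  // weight-free kinetic rates for the cybernetic control
  const double rho_xyl_kin = p.km * xyl / (xyl + p.Ks_xyl) * X;
  double rho_glu2_kin = 0.0;
  if (p.diauxic)
    rho_glu2_kin = p.km2 * e2 * glu / (glu + p.Ks_glu2) * X;

  double v1 = 1.0, v2 = 0.0, u = 0.0;
  if (p.diauxic) {
    const double mx = std::max(rho_xyl_kin, rho_glu2_kin);
    if (mx > 0.0) {
      v1 = rho_xyl_kin / mx;
      v2 = rho_glu2_kin / mx;
      u  = rho_glu2_kin / (rho_xyl_kin + rho_glu2_kin);
    } else {
      v1 = 1.0; v2 = 1.0; u = 0.0; // degenerate: all rates are zero anyway
    }
  }

  const double rho_glu  = p.km * glu / (glu + p.Ks_glu) * X * v1;
  const double rho_xyl  = rho_xyl_kin * v1;
  const double rho_ara  = p.km * ara / (ara + p.Ks_ara) * X * v1;
  const double rho_glu2 = rho_glu2_kin * v2;
  double rho_E = 0.0;
  if (p.diauxic) {
    const double gn = std::pow(glu, p.n_hill);
    const double kn = std::pow(p.Ks_E2, p.n_hill);
    rho_E = p.alpha * gn / (gn + kn) * X * u;
  }

  const double sum_rho = rho_glu + rho_glu2 + rho_xyl + rho_ara;

  // carbonate speciation (fast, drives co2aq <-> co2sol)
  const double frac = std::pow(10.0, p.pH - p.pK1) +
                      std::pow(10.0, 2.0 * p.pH - p.pK1 - p.pK2);
  const double rho_ab = p.k_AB * (co2aq * frac - co2sol);

  // gas-liquid transfer (partial pressures in Pa)
  const double p_h2  = h2g  * p.R_gas * p.T * 101325.0;
  const double p_co2 = co2g * p.R_gas * p.T * 101325.0;
  const double rho_t_h2  = p.kla_h2  * (h2aq  - p_h2  * p.KH_h2);
  const double rho_t_co2 = p.kla_co2 * (co2aq - p_co2 * p.KH_co2);

  // headspace outflow (L/h); product gas volumetric rate at reactor T, 1 atm
  double qgas = p.N2;
  if (p.qgas_mode == 0) {
    const double prod = p.V_liq * (rho_t_h2 + rho_t_co2) * p.R_gas * p.T;
    qgas += std::max(0.0, prod);
  }
  if (qgas_out) *qgas_out = qgas;

  const double om_Yx = 1.0 - p.Y_x;

  dy[I_GLU]    = -rho_glu - rho_glu2;
  dy[I_XYL]    = -rho_xyl;
  dy[I_ARA]    = -rho_ara;
  dy[I_X]      = p.Y_x * sum_rho - p.r_cd * X;
  dy[I_AC]     = om_Yx * p.Y_ac * sum_rho;
  dy[I_H2AQ]   = om_Yx * p.Y_h2 * sum_rho - rho_t_h2;
  dy[I_CO2AQ]  = om_Yx * p.Y_co2 * sum_rho - rho_t_co2 - rho_ab;
  dy[I_CO2SOL] = rho_ab;
  dy[I_H2G]    = p.V_liq / p.V_gas * rho_t_h2  - h2g  * qgas / p.V_gas;
  dy[I_CO2G]   = p.V_liq / p.V_gas * rho_t_co2 - co2g * qgas / p.V_gas;
  dy[I_E2]     = p.diauxic ? (rho_E - p.beta * e2 - e2 * rho_glu2) : 0.0;
  // cumulative bookkeeping pools (per liquid volume)
  dy[I_H2OUT]  = qgas * h2g  / p.V_liq;
  dy[I_CO2OUT] = qgas * co2g / p.V_liq;
  dy[I_XDEAD]  = p.r_cd * X;
}

// Forward-difference Jacobian.
static void num_jacobian(const arma::vec& y, const Pars& p, arma::mat& J) {
  arma::vec f0(NS), f1(NS), yp(NS);
  rhs(y, p, f0, nullptr);
  const double sq = std::sqrt(std::numeric_limits<double>::epsilon());
  for (int j = 0; j < NS; ++j) {
    yp = y;
    double h = sq * std::max(std::abs(y[j]), 1e-6);
    yp[j] += h;
    rhs(yp, p, f1, nullptr);
    J.col(j) = (f1 - f0) / h;
  }
}

// [[Rcpp::export]]
List rhs_point_cpp(NumericVector y, NumericVector kin, NumericVector cons,
                   bool diauxic, int qgas_mode) {
  Pars p = unpack(kin, cons, diauxic, qgas_mode);
  arma::vec yy(y.begin(), NS), dy(NS);
  double qgas = 0.0;
  rhs(yy, p, dy, &qgas);
  return List::create(_["dydt"] = NumericVector(dy.begin(), dy.end()),
                      _["q_gas"] = qgas);
}

// [[Rcpp::export]]
List simulate_cpp(NumericVector y0, NumericVector tgrid, NumericVector kin,
                  NumericVector cons, bool diauxic, int qgas_mode,
                  double rtol, double atol, double max_steps) {
  Pars p = unpack(kin, cons, diauxic, qgas_mode);
  const int nt = tgrid.size();
  arma::mat out(nt, NS);
  NumericVector qgas_out(nt);

  arma::vec y(y0.begin(), NS);
  for (int i = 0; i < NS; ++i)
    if (!std::isfinite(y[i]))
      stop("non-finite state in initial condition (component %d)", i + 1);

  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);

  arma::vec f0(NS), f1(NS), f2(NS), k1(NS), k2(NS), k3(NS), ynew(NS),
      err(NS);
  arma::mat J(NS, NS), W(NS, NS);
  const arma::mat I = arma::eye(NS, NS);

  double t = tgrid[0];
  double qg0;
  rhs(y, p, f0, &qg0);
  out.row(0) = y.t();
  qgas_out[0] = qg0;

  double h = 1e-6;
  long nacc = 0, nrej = 0;
  int iout = 1;

  while (iout < nt) {
    const double tend = tgrid[nt - 1];
    if (t + h > tend) h = tend - t;
    if (h < 1e-13) h = 1e-13;

    rhs(y, p, f0, nullptr);
    num_jacobian(y, p, J);
    W = I - (h * d) * J;
    bool ok = true;
    k1 = arma::solve(W, f0, arma::solve_opts::fast);
    arma::vec ymid = y + 0.5 * h * k1;
    rhs(ymid, p, f1, nullptr);
    k2 = arma::solve(W, f1 - k1, arma::solve_opts::fast) + k1;
    ynew = y + h * k2;
    rhs(ynew, p, f2, nullptr);
    k3 = arma::solve(W, f2 - e32 * (k2 - f1) - 2.0 * (k1 - f0),
                     arma::solve_opts::fast);
    err = (h / 6.0) * (k1 - 2.0 * k2 + k3);

    double errnorm = 0.0;
    for (int i = 0; i < NS; ++i) {
      const double sc =
          atol + rtol * std::max(std::abs(y[i]), std::abs(ynew[i]));
      const double e = std::abs(err[i]) / sc;
      if (e > errnorm) errnorm = e;
      if (!std::isfinite(ynew[i])) ok = false;
    }
    if (!ok) errnorm = 1e10;

    if (errnorm <= 1.0) {
      // accept; emit any grid points inside (t, t+h] by linear blending of
      // the Rosenbrock step (dense output via cubic Hermite on f0/f2)
      const double tnew = t + h;
      while (iout < nt && tgrid[iout] <= tnew + 1e-12) {
        const double s = (tgrid[iout] - t) / h;
        // cubic Hermite interpolation
        const double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
        const double h10 = s * (1 - s) * (1 - s);
        const double h01 = s * s * (3 - 2 * s);
        const double h11 = s * s * (s - 1);
        arma::vec yi = h00 * y + h10 * h * f0 + h01 * ynew + h11 * h * f2;
        arma::vec dtmp(NS);
        double qg;
        rhs(yi, p, dtmp, &qg);
        out.row(iout) = yi.t();
        qgas_out[iout] = qg;
        ++iout;
      }
      t = tnew;
      y = ynew;
      ++nacc;
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -1.0 / 3.0);
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      ++nrej;
      double fac = 0.9 * std::pow(errnorm, -1.0 / 3.0);
      h *= std::min(0.5, std::max(0.1, fac));
      if (h < 1e-13)
        stop("integration failure: step size underflow at t = %g h", t);
    }
    if (nacc + nrej > max_steps)
      stop("integration failure: step budget exceeded at t = %g h", t);
  }

  return List::create(_["y"] = wrap(out), _["q_gas"] = qgas_out,
                      _["n_accept"] = (double)nacc,
                      _["n_reject"] = (double)nrej);
}
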