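#include <Rcpp.h>
using namespace Rcpp;

// Velocity-storage / somatogravic state estimator.
//
// State: VS (3-vector, deg/s) and G (3-vector, unit length).
// Per-sample inputs: Vis (visual scene angular velocity, deg/s), V (canal
// signal, deg/s), GIA (unit gravito-inertial direction). Inputs are treated
// as piecewise constant over each integration step.
//
// The direct pathway is resolved algebraically each step:
//   Omega = (go*Vis + gv*V + VS) / (1 + go),  rSL = Vis - Omega
// so that Omega = go*rSL + gv*V + VS holds exactly without a one-step delay.
//
//   dVS/dt = ko*rSL + kv*V - VS/t_vs + kf*(GIA x G)
//   dG/dt  = G x Omega_rad - (G - GIA)/t_s
//
// Gains act on deg/s signals; Omega is converted to rad/s for the rotation
// of the direction vector G. Fixed-step classical RK4; G is renormalised
// after every step and the worst pre-renormalisation drift is reported.

static const double kDegToRad = M_PI / 180.0;

struct Deriv {
  double dvs[3];
  double dg[3];
};

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline void deriv(const double* vs, const double* g,
                         const double* vis, const double* v,
                         const double* gia,
                         double ko, double kv, double go, double gv,
                         double kf, double t_vs, double t_s,
                         Deriv& d, double* omega_out) {
  double omega[3], omega_rad[3], rsl[3], fb[3], gxo[3];
  for (int k = 0; k < 3; ++k) {
    omega[k] = (go * vis[k] + gv * v[k] + vs[k]) / (1.0 + go);
    rsl[k] = vis[k] - omega[k];
    omega_rad[k] = omega[k] * kDegToRad;
  }
  cross3(gia, g, fb);
  cross3(g, omega_rad, gxo);
  for (int k = 0; k < 3; ++k) {
    d.dvs[k] = ko * rsl[k] + kv * v[k] - vs[k] / t_vs + kf * fb[k];
    d.dg[k] = gxo[k] - (g[k] - gia[k]) / t_s;
    if (omega_out) omega_out[k] = omega[k];
  }
  // G encodes a direction: remove the radial (norm-changing) component of
  // its derivative, so the flow stays on the unit sphere and the direction
  // dynamics are untouched
  double gg = 0.0, dgg = 0.0;
  for (int k = 0; k < 3; ++k) { gg += g[k] * g[k]; dgg += d.dg[k] * g[k]; }
  for (int k = 0; k < 3; ++k) d.dg[k] -= dgg / gg * g[k];
}

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(NumericMatrix vis, NumericMatrix v, NumericMatrix gia,
                  NumericVector vs0, NumericVector g0,
                  double ko, double kv, double go, double gv,
                  double kf, double t_vs, double t_s, double dt) {
  const int n = vis.nrow();
  if (v.nrow() != n || gia.nrow() != n)
    stop("input series must share one time grid");
  if (dt <= 0) stop("dt must be > 0");

  NumericMatrix g_out(n, 3), vs_out(n, 3), omega_out(n, 3);
  double vs[3], g[3];
  for (int k = 0; k < 3; ++k) { vs[k] = vs0[k]; g[k] = g0[k]; }

  double max_drift = 0.0;
  double in_vis[3], in_v[3], in_gia[3], omega[3];
  Deriv k1, k2, k3, k4;
  double vs_t[3], g_t[3];

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      in_vis[k] = vis(i, k); in_v[k] = v(i, k); in_gia[k] = gia(i, k);
    }
    // record state (and the self-consistent Omega) at sample i
    deriv(vs, g, in_vis, in_v, in_gia, ko, kv, go, gv, kf, t_vs, t_s,
          k1, omega);
    for (int k = 0; k < 3; ++k) {
      g_out(i, k) = g[k]; vs_out(i, k) = vs[k]; omega_out(i, k) = omega[k];
    }
    if (i == n - 1) break;

    // classical RK4 with inputs held constant over the step
    for (int k = 0; k < 3; ++k) {
      vs_t[k] = vs[k] + 0.5 * dt * k1.dvs[k];
      g_t[k] = g[k] + 0.5 * dt * k1.dg[k];
    }
    deriv(vs_t, g_t, in_vis, in_v, in_gia, ko, kv, go, gv, kf, t_vs, t_s,
          k2, nullptr);
    for (int k = 0; k < 3; ++k) {
      vs_t[k] = vs[k] + 0.5 * dt * k2.dvs[k];
      g_t[k] = g[k] + 0.5 * dt * k2.dg[k];
    }
    deriv(vs_t, g_t, in_vis, in_v, in_gia, ko, kv, go, gv, kf, t_vs, t_s,
          k3, nullptr);
    for (int k = 0; k < 3; ++k) {
      vs_t[k] = vs[k] + dt * k3.dvs[k];
      g_t[k] = g[k] + dt * k3.dg[k];
    }
    deriv(vs_t, g_t, in_vis, in_v, in_gia, ko, kv, go, gv, kf, t_vs, t_s,
          k4, nullptr);

    double norm2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      vs[k] += dt / 6.0 * (k1.dvs[k] + 2.0 * k2.dvs[k] +
                           2.0 * k3.dvs[k] + k4.dvs[k]);
      g[k] += dt / 6.0 * (k1.dg[k] + 2.0 * k2.dg[k] +
                          2.0 * k3.dg[k] + k4.dg[k]);
      norm2 += g[k] * g[k];
    }
    double nrm = std::sqrt(norm2);
    double drift = std::fabs(nrm - 1.0);
    if (drift > max_drift) max_drift = drift;
    for (int k = 0; k < 3; ++k) g[k] /= nrm;
  }

  return List::create(_["g"] = g_out, _["vs"] = vs_out,
                      _["omega"] = omega_out, _["max_drift"] = max_drift);
}
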