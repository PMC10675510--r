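// Explicit finite-difference (Euler) integrator for the 1D
// diffusion-partition-metabolism model of a cell layer on a transwell
// membrane, with periodic basal sampling events.
//
// Internal units: length um, time min, concentration uM, volume uL,
// area cm^2, amount nmol. Conversion constant: A[cm^2] * D[um^2/min] *
// grad[uM/um] = 1e-4 nmol/min (1 cm^2*um = 0.1 uL, 1 uM = 1e-3 nmol/uL).
//
// Boundary handling: the apical node is a Dirichlet value Kcell*ca,
// refreshed from the apical ODE by operator splitting each step; the basal
// node uses a ghost point enforcing equality of the intra-layer diffusive
// flux and the transwell-membrane flux P0*(cB/Kcell - cb).

#include <Rcpp.h>
using namespace Rcpp;

static double trapz(const std::vector<double>& c, double dh) {
  double s = 0.0;
  for (size_t j = 1; j < c.size(); ++j) s += 0.5 * (c[j - 1] + c[j]) * dh;
  return s;
}

// [[Rcpp::export(name = ".barrier_euler_cpp")]]
List barrier_euler_cpp(double D, double Kcell, double P0, double M,
                       double H, int n_nodes, double dt_factor,
                       double ca0, double Va, double Vb, double A,
                       NumericVector sample_times,
                       bool hold_reservoirs, double cb_fixed) {
  const int n = n_nodes;
  const double dh = H / (n - 1);
  const double dt_max = dt_factor * dh * dh / D;
  const double FH = 1e-4 * A;       // nmol/min per (um^2/min * uM/um)
  const double Mflux = M * A;       // nmol/min drained from the apical side

  std::vector<double> c(n, 0.0), cnew(n, 0.0);
  double ca = ca0;
  double cb = hold_reservoirs ? cb_fixed : 0.0;
  double metabolized = 0.0, collected = 0.0;

  const int ns = sample_times.size();
  NumericVector J(ns), ca_series(ns), N_series(ns), cb_series(ns),
      met_series(ns);

  double t = 0.0;
  for (int s = 0; s < ns; ++s) {
    const double t_end = sample_times[s];
    const double span = t_end - t;
    if (span <= 0) stop("sample times must be strictly increasing");
    const int nsteps = (int)std::ceil(span / dt_max);
    const double dt = span / nsteps;
    const double r = D * dt / (dh * dh);

    for (int step = 0; step < nsteps; ++step) {
      c[0] = Kcell * ca;                       // apical Dirichlet
      // ghost node: -D dc/dh|H = P0*(c[n-1]/Kcell - cb)
      const double cg = c[n - 2] -
        2.0 * dh * (P0 / D) * (c[n - 1] / Kcell - cb);
      for (int j = 1; j < n - 1; ++j)
        cnew[j] = c[j] + r * (c[j + 1] - 2.0 * c[j] + c[j - 1]);
      cnew[n - 1] = c[n - 1] + r * (cg - 2.0 * c[n - 1] + c[n - 2]);
      cnew[0] = c[0];

      // apical balance: second-order one-sided gradient at h = 0
      const double g0 = (-3.0 * c[0] + 4.0 * c[1] - c[2]) / (2.0 * dh);
      const double Fb = FH * P0 * (c[n - 1] / Kcell - cb); // nmol/min

      if (!hold_reservoirs) {
        double ca_diff = ca + FH * D * g0 * dt * 1000.0 / Va;
        if (ca_diff < 0.0) ca_diff = 0.0;      // numerical safety
        // metabolism clamp: never drive ca negative within a step
        double met = Mflux * dt;               // nmol
        const double avail = ca_diff * Va / 1000.0;
        if (met > avail) met = avail;
        metabolized += met;
        ca = ca_diff - met * 1000.0 / Va;
        cb += Fb * dt * 1000.0 / Vb;
        if (cb < 0.0) cb = 0.0;
      }
      c.swap(cnew);
      t += dt;
    }

    if (hold_reservoirs) {
      // reservoir mode: report the instantaneous membrane flux (nmol/min)
      J[s] = FH * P0 * (c[n - 1] / Kcell - cb);
    } else {
      J[s] = cb * Vb / 1000.0;                 // collected amount, nmol
      collected += J[s];
      cb = 0.0;                                // medium replacement
    }
    ca_series[s] = ca;
    N_series[s] = 1e-4 * A * trapz(c, dh);     // nmol within the layer
    cb_series[s] = cb;
    met_series[s] = metabolized;
  }

  return List::create(_["J"] = J, _["ca_series"] = ca_series,
                      _["N_series"] = N_series, _["cb_series"] = cb_series,
                      _["met_series"] = met_series,
                      _["profile"] = NumericVector(c.begin(), c.end()),
                      _["metabolized"] = metabolized,
                      _["collected"] = collected, _["t"] = t);
}
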