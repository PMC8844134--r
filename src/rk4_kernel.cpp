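#include <Rcpp.h>
#include <cmath>

// Fixed-step RK4 for the learning-modulated consumption dynamics,
// vectorised over the offered-prey grid: every grid value is an
// independent scalar ODE, so the whole response curve is advanced in one
// loop over time steps.
//
// Constant density (Holling):  dN/dt  =  a(N) D / (1 + a(N) h(N) D)
// Prey depletion (Rogers):     dNa/dt = -a(N) Na / (1 + a(N) h(N) Na),
//                              N = N0 - Na
// with the learning curves substituted in closed form:
//   a(N) = am - (am - a0) exp(-la N),  h(N) = hm + (h0 - hm) exp(-lh N).

namespace {

struct Learn {
  double a0, am, la, h0, hm, lh;
  double da, dh;  // amplitudes
  inline double a(double N) const {
    return (da == 0.0 || la == 0.0) ? a0 : am - da * std::exp(-la * N);
  }
  inline double h(double N) const {
    // lh = 0 freezes h at h0 (no learning), not at the asymptote hm
    return (dh == 0.0) ? hm : (lh == 0.0 ? h0 : hm + dh * std::exp(-lh * N));
  }
};

inline double rate_holling(const Learn &p, double N, double D) {
  double a = p.a(N), h = p.h(N);
  return a * D / (1.0 + a * h * D);
}

inline double rate_rogers(const Learn &p, double Na, double N0) {
  if (Na <= 0.0) return 0.0;
  double N = N0 - Na;
  double a = p.a(N), h = p.h(N);
  return -a * Na / (1.0 + a * h * Na);
}

}  // namespace

// [[Rcpp::export(name = ".rk4_consumed_grid")]]
Rcpp::NumericVector rk4_consumed_grid(double a0, double am, double la,
                                      double h0, double hm, double lh,
                                      Rcpp::NumericVector offered,
                                      double dt, int n_steps,
                                      bool depletion) {
  const int m = offered.size();
  Learn p{a0, am, la, h0, hm, lh, am - a0, h0 - hm};
  Rcpp::NumericVector out(m);

  for (int j = 0; j < m; ++j) {
    const double D = offered[j];
    double y = depletion ? D : 0.0;  // state: Na (depletion) or N (Holling)
    for (int s = 0; s < n_steps; ++s) {
      double k1, k2, k3, k4;
      if (depletion) {
        k1 = rate_rogers(p, y, D);
        k2 = rate_rogers(p, y + 0.5 * dt * k1, D);
        k3 = rate_rogers(p, y + 0.5 * dt * k2, D);
        k4 = rate_rogers(p, y + dt * k3, D);
      } else {
        k1 = rate_holling(p, y, D);
        k2 = rate_holling(p, y + 0.5 * dt * k1, D);
        k3 = rate_holling(p, y + 0.5 * dt * k2, D);
        k4 = rate_holling(p, y + dt * k3, D);
      }
      y += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      if (!std::isfinite(y))
        Rcpp::stop("non-finite state at step %d (offered = %g)", s + 1, D);
      if (depletion) {
        if (y < -1e-9)
          Rcpp::stop("available prey fell below zero at step %d "
                     "(offered = %g)", s + 1, D);
        if (y < 0.0) y = 0.0;  // clamp within tolerance
      }
    }
    out[j] = depletion ? D - y : y;
  }
  return out;
}
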