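#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integration of the 8-species Hes/ID/proneural circuit by the
// method of steps. The only delayed quantity is the Hes-Hes homodimer p2
// entering the auto-repression Hill term; its history is kept on the step grid
// and looked up by Catmull-Rom (cubic Hermite with finite-difference slopes)
// interpolation. History for t < 0 is constant at the initial state.

namespace {

struct Pars {
  double m0, p0, gm, gp, k, ti, n, h0, eps, f, ID, I, ma0, pa0, ga;
};

inline double hill_plus(double x, double h0, double n) {
  if (x <= 0.0) return 0.0;
  double r = std::pow(x / h0, n);
  return r / (1.0 + r);
}

inline double hill_minus(double x, double h0, double n) {
  return 1.0 - hill_plus(x, h0, n);
}

// y: m, p, p2, pid, ma, a, a2, aid
inline void rhs(const double* y, double p2_delayed, const Pars& P, double* dy) {
  double hs = hill_minus(p2_delayed, P.h0, P.n) + P.f * hill_plus(p2_delayed, P.h0, P.n);
  double hp_I = hill_plus(P.I, P.h0, P.n);
  double m = y[0], p = y[1], p2 = y[2], pid = y[3];
  double ma = y[4], a = y[5], a2 = y[6], aid = y[7];

  dy[0] = P.m0 * hp_I * hs - P.gm * m;
  dy[1] = P.p0 * m - P.gp * p - 2.0 * P.k * p * p - P.k * p * P.ID;
  dy[2] = P.k * p * p - P.gp * p2;
  dy[3] = P.k * p * P.ID - P.gp * pid;

  double repressor = p2 + P.eps * pid;  // pooled, not delayed
  dy[4] = P.ma0 * hill_minus(repressor, P.h0, P.n) - P.ga * ma;
  dy[5] = P.pa0 * ma - P.ga * a - 2.0 * P.k * a * a - P.k * a * P.ID;
  dy[6] = P.k * a * a - P.ga * a2;
  dy[7] = P.k * a * P.ID - P.ga * aid;
}

// Catmull-Rom lookup of the delayed p2. `filled` is the index of the last
// stored grid point; `fallback` is the current stage value, used when the
// delayed time lands at/after the integration front (delay shorter than dt).
inline double lookup_p2(const std::vector<double>& hist, int filled, double dt,
                        double td, double p2_init, double fallback) {
  if (td <= 0.0) return p2_init;
  double s = td / dt;
  int j = static_cast<int>(std::floor(s));
  double th = s - j;
  if (j >= filled) return fallback;
  double p1 = hist[j], p2v = hist[j + 1];
  if (th == 0.0) return p1;
  double p0 = (j >= 1) ? hist[j - 1] : p1;
  double p3 = (j + 2 <= filled) ? hist[j + 2] : p2v;
  // Catmull-Rom tangents; reproduces linear data exactly
  double m1 = 0.5 * (p2v - p0);
  double m2 = 0.5 * (p3 - p1);
  double th2 = th * th, th3 = th2 * th;
  return (2.0 * th3 - 3.0 * th2 + 1.0) * p1 + (th3 - 2.0 * th2 + th) * m1 +
         (-2.0 * th3 + 3.0 * th2) * p2v + (th3 - th2) * m2;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix integrate_circuit_cpp(NumericVector y0, NumericVector pars,
                                    double t_end, double dt) {
  Pars P;
  P.m0 = pars["m0"];   P.p0 = pars["p0"];   P.gm = pars["gm"];
  P.gp = pars["gp"];   P.k = pars["k"];     P.ti = pars["t_i"];
  P.n = pars["n"];     P.h0 = pars["h0"];   P.eps = pars["eps"];
  P.f = pars["f"];     P.ID = pars["ID"];   P.I = pars["I"];
  P.ma0 = pars["ma0"]; P.pa0 = pars["pa0"]; P.ga = pars["ga"];

  const int nspec = 8;
  int nsteps = static_cast<int>(std::round(t_end / dt));
  NumericMatrix out(nsteps + 1, nspec + 1);
  std::vector<double> hist(nsteps + 1);

  double y[8], k1[8], k2[8], k3[8], k4[8], tmp[8];
  for (int i = 0; i < nspec; ++i) y[i] = y0[i];
  double p2_init = y0[2];

  out(0, 0) = 0.0;
  for (int i = 0; i < nspec; ++i) out(0, i + 1) = y[i];
  hist[0] = y[2];

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    int filled = step;

    double d1 = lookup_p2(hist, filled, dt, t - P.ti, p2_init, y[2]);
    rhs(y, d1, P, k1);

    for (int i = 0; i < nspec; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    double d2 = lookup_p2(hist, filled, dt, t + 0.5 * dt - P.ti, p2_init, tmp[2]);
    rhs(tmp, d2, P, k2);

    for (int i = 0; i < nspec; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    double d3 = lookup_p2(hist, filled, dt, t + 0.5 * dt - P.ti, p2_init, tmp[2]);
    rhs(tmp, d3, P, k3);

    for (int i = 0; i < nspec; ++i) tmp[i] = y[i] + dt * k3[i];
    double d4 = lookup_p2(hist, filled, dt, t + dt - P.ti, p2_init, tmp[2]);
    rhs(tmp, d4, P, k4);

    double t_next = (step + 1) * dt;
    for (int i = 0; i < nspec; ++i) {
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(y[i]))
        stop("integration failure: non-finite state at t = %f min", t_next);
      if (y[i] < 0.0) {
        if (y[i] > -1e-9) y[i] = 0.0;  // round-off excursion
        else stop("integration failure: negative state (%.3e) at t = %f min",
                  y[i], t_next);
      }
    }
    hist[step + 1] = y[2];
    out(step + 1, 0) = t_next;
    for (int i = 0; i < nspec; ++i) out(step + 1, i + 1) = y[i];
  }
  return out;
}
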