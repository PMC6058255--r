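#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Turnover cascade LPS -> TNF-a -> {IL-6, iNOS -> NO}.
//
// State order: y[0] TNF-a, y[1] IL-6, y[2] iNOS (relative ratio), y[3] NO.
// TNF-a is autonomous and linear, so its exact solution is used for the
// delayed lookups TNF(t - tau1), TNF(t - tau2); the pre-stimulus history is
// TNF(t) = tnf0 for t <= 0.  The four states are integrated jointly with an
// adaptive Dormand-Prince 5(4) stepper; integration is split at the delay
// kink points tau1, tau2 where the right-hand side is non-smooth.

struct Pars {
  double k_in_tnf, k_out_tnf, k_in_il6, k_out_il6, tau1;
  double k_in_inos, k_out_inos, tau2, k_in_no, k_out_no, delta;
  double tnf0, il6_0, inos0, no0;
  double f; // inhibition fraction alpha * ln(C), constant per arm
};

static inline double tnf_exact(const Pars &p, double t) {
  if (t <= 0.0) return p.tnf0;
  double S = p.k_in_tnf * (1.0 - p.f);
  if (p.k_out_tnf > 0.0) {
    double A = S / p.k_out_tnf;
    return A + (p.tnf0 - A) * std::exp(-p.k_out_tnf * t);
  }
  return p.tnf0 + S * t;
}

static inline void rhs(const Pars &p, double t, const double *y, double *dy) {
  dy[0] = p.k_in_tnf * (1.0 - p.f) - p.k_out_tnf * y[0];
  dy[1] = p.k_in_il6 * tnf_exact(p, t - p.tau1) - p.k_out_il6 * y[1];
  dy[2] = p.k_in_inos * tnf_exact(p, t - p.tau2) - p.k_out_inos * y[2];
  double inos = y[2] > 0.0 ? y[2] : 0.0; // pow of tiny negative overshoot
  dy[3] = p.k_in_no * std::pow(inos, p.delta) - p.k_out_no * y[3];
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// integrate y from t0 to t1 in place; false on step-size collapse
static bool dp45(const Pars &p, double t0, double t1, double *y, double rtol,
                 double atol) {
  const int n = 4;
  double t = t0, h = (t1 - t0) * 0.1;
  if (t1 <= t0) return true;
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4], yt[4], y5[4];
  rhs(p, t, y, k1);
  long nsteps = 0;
  while (t < t1) {
    if (++nsteps > 200000) return false;
    if (t + h > t1) h = t1 - t;
    for (int i = 0; i < n; i++) yt[i] = y[i] + h * a21 * k1[i];
    rhs(p, t + c2 * h, yt, k2);
    for (int i = 0; i < n; i++) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(p, t + c3 * h, yt, k3);
    for (int i = 0; i < n; i++)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(p, t + c4 * h, yt, k4);
    for (int i = 0; i < n; i++)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(p, t + c5 * h, yt, k5);
    for (int i = 0; i < n; i++)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    rhs(p, t + h, yt, k6);
    for (int i = 0; i < n; i++)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
    rhs(p, t + h, y5, k7);
    double err = 0.0;
    for (int i = 0; i < n; i++) {
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                      e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) return false;
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < n; i++) {
        y[i] = y5[i];
        k1[i] = k7[i]; // FSAL
      }
    }
    double fac = 0.9 * std::pow(err > 1e-10 ? err : 1e-10, -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h < 1e-13) return false;
  }
  return true;
}

// [[Rcpp::export]]
NumericMatrix cascade_solve_cpp(NumericVector pv, double f, NumericVector times,
                                double rtol, double atol) {
  if (pv.size() != 15) stop("expected 15 parameter values");
  Pars p;
  p.k_in_tnf = pv[0];  p.k_out_tnf = pv[1];
  p.k_in_il6 = pv[2];  p.k_out_il6 = pv[3];  p.tau1 = pv[4];
  p.k_in_inos = pv[5]; p.k_out_inos = pv[6]; p.tau2 = pv[7];
  p.k_in_no = pv[8];   p.k_out_no = pv[9];   p.delta = pv[10];
  p.tnf0 = pv[11]; p.il6_0 = pv[12]; p.inos0 = pv[13]; p.no0 = pv[14];
  p.f = f;
  if (f >= 1.0) stop("inhibition fraction >= 1: negative production");
  const int nt = times.size();
  NumericMatrix out(nt, 4);
  double y[4] = {p.tnf0, p.il6_0, p.inos0, p.no0};
  double tcur = 0.0;
  std::vector<double> brk;
  if (p.tau1 > 0) brk.push_back(p.tau1);
  if (p.tau2 > 0 && p.tau2 != p.tau1) brk.push_back(p.tau2);
  for (int j = 0; j < nt; j++) {
    double tj = times[j];
    if (j > 0 && tj < times[j - 1]) stop("times must be non-decreasing");
    if (tj < 0) stop("times must be >= 0");
    while (tcur < tj) {
      double tnext = tj;
      for (size_t b = 0; b < brk.size(); b++)
        if (brk[b] > tcur + 1e-14 && brk[b] < tnext) tnext = brk[b];
      if (!dp45(p, tcur, tnext, y, rtol, atol))
        stop("cascade integrator failed (step size collapse)");
      tcur = tnext;
    }
    for (int i = 0; i < 4; i++) out(j, i) = y[i];
  }
  return out;
}
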