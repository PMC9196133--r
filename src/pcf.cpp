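// Evaluation of Phi_w(x) = exp(x^2/4) * U(i*nu - 1/2, x) and its x-derivative,
// where U is the parabolic cylinder function and nu = omega * tau_m >= 0.
//
// Phi satisfies Phi'' = x Phi' + i nu Phi and is the solution recessive at
// x -> +infinity, where Phi ~ x^{-i nu} (modulus 1). The exp(x^2/4) factor is
// fused analytically: it never appears as an explicit product.
//
// Scheme: start at z0 (to the right of all requested points) from the
// asymptotic expansion
//   Phi(z) = z^{-i nu} sum_s (-1)^s (i nu)_{2s} / (s! (2 z^2)^s),
// then integrate the ODE backward with an adaptive Dormand-Prince RK45 step.
// Backward integration is stable: the contaminating solution (~exp(z^2/2))
// decays toward smaller z, and for z < 0 Phi itself becomes the dominant
// solution. State is renormalized on the fly; a separate log-scale per
// output point keeps values representable for |x| up to ~100.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <algorithm>
#include <cmath>

using cplx = std::complex<double>;

struct State { cplx phi, dphi; };

static inline State ode_rhs(double z, const State& y, const cplx& inu) {
  State d;
  d.phi = y.dphi;
  d.dphi = z * y.dphi + inu * y.phi;
  return d;
}

// asymptotic series at z > 0; returns true on convergence to ~1e-15
static bool phi_asymptotic(double nu, double z, State& out) {
  const cplx inu(0.0, nu);
  const double z2inv = 1.0 / (2.0 * z * z);
  cplx term(1.0, 0.0);
  cplx S = term;
  cplx Sd = term * (-inu); // sum of c_s * (-i nu - 2 s) z^{-2s}
  bool ok = false;
  for (int s = 1; s <= 80; ++s) {
    cplx factor = (inu + cplx(2.0 * (s - 1), 0.0)) *
                  (inu + cplx(2.0 * s - 1.0, 0.0));
    term *= -factor * z2inv / static_cast<double>(s);
    S += term;
    Sd += term * (-inu - cplx(2.0 * s, 0.0));
    double t = std::abs(term);
    if (t < 1e-16 * std::abs(S)) { ok = true; break; }
    if (t > 1e6) break; // diverging: z too small for this nu
  }
  if (!ok) return false;
  // Phi = z^{-i nu} S;  Phi' = z^{-i nu - 1} Sd
  double lz = std::log(z);
  cplx zpow = std::exp(cplx(0.0, -nu * lz));
  out.phi = zpow * S;
  out.dphi = zpow * Sd / z;
  return true;
}

// one Dormand-Prince RK45 step; returns embedded error estimate
static double dp45_step(double z, double h, const State& y, const cplx& inu,
                        State& ynew) {
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
  static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                      e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                      e6 = 187.0 / 2100, e7 = 1.0 / 40;

  auto lin = [](const State& y, double w, const State& k) {
    State r; r.phi = y.phi + w * k.phi; r.dphi = y.dphi + w * k.dphi; return r;
  };
  State k1 = ode_rhs(z, y, inu);
  State t = lin(y, h * a21, k1);
  State k2 = ode_rhs(z + c2 * h, t, inu);
  t = lin(lin(y, h * a31, k1), h * a32, k2);
  State k3 = ode_rhs(z + c3 * h, t, inu);
  t = lin(lin(lin(y, h * a41, k1), h * a42, k2), h * a43, k3);
  State k4 = ode_rhs(z + c4 * h, t, inu);
  t = lin(lin(lin(lin(y, h * a51, k1), h * a52, k2), h * a53, k3), h * a54, k4);
  State k5 = ode_rhs(z + c5 * h, t, inu);
  t = lin(lin(lin(lin(lin(y, h * a61, k1), h * a62, k2), h * a63, k3),
              h * a64, k4), h * a65, k5);
  State k6 = ode_rhs(z + h, t, inu);

  ynew.phi = y.phi + h * (b1 * k1.phi + b3 * k3.phi + b4 * k4.phi +
                          b5 * k5.phi + b6 * k6.phi);
  ynew.dphi = y.dphi + h * (b1 * k1.dphi + b3 * k3.dphi + b4 * k4.dphi +
                            b5 * k5.dphi + b6 * k6.dphi);
  State k7 = ode_rhs(z + h, ynew, inu);
  cplx err_phi = ynew.phi - (y.phi + h * (e1 * k1.phi + e3 * k3.phi +
                 e4 * k4.phi + e5 * k5.phi + e6 * k6.phi + e7 * k7.phi));
  cplx err_dphi = ynew.dphi - (y.dphi + h * (e1 * k1.dphi + e3 * k3.dphi +
                  e4 * k4.dphi + e5 * k5.dphi + e6 * k6.dphi + e7 * k7.dphi));
  double sc1 = std::abs(ynew.phi) + std::abs(y.phi) + 1e-290;
  double sc2 = std::abs(ynew.dphi) + std::abs(y.dphi) + 1e-290;
  return std::max(std::abs(err_phi) / sc1, std::abs(err_dphi) / sc2);
}

// [[Rcpp::export]]
Rcpp::List pcf_phi_cpp(double nu, Rcpp::NumericVector x, double rtol = 1e-12) {
  if (nu < 0) Rcpp::stop("pcf_phi_cpp: nu must be >= 0");
  const int n = x.size();
  const cplx inu(0.0, nu);

  // requested points sorted descending
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] > x[b]; });

  double xmax = n ? x[ord[0]] : 0.0;
  double z0 = std::max({xmax + 1.0, 8.0, 0.72 * nu});
  State y;
  int guard = 0;
  while (!phi_asymptotic(nu, z0, y)) {
    z0 *= 1.35;
    if (++guard > 60) Rcpp::stop("pcf: asymptotic start failed (nu=%g)", nu);
  }

  Rcpp::ComplexVector phi_out(n), dphi_out(n);
  Rcpp::NumericVector ls_out(n);

  double z = z0;
  double logscale = 0.0;
  double h = -std::min(0.05, 1.0 / (1.0 + nu)); // negative: backward
  const double hmin = 1e-10;

  for (int idx = 0; idx < n; ++idx) {
    double target = x[ord[idx]];
    if (target > z0) Rcpp::stop("pcf: internal ordering error");
    while (z > target + 1e-14 * std::max(1.0, std::fabs(target))) {
      double hstep = h;
      if (z + hstep < target) hstep = target - z;
      State ynew;
      double err = dp45_step(z, hstep, y, inu, ynew);
      if (err <= rtol || std::fabs(hstep) <= hmin) {
        z += hstep;
        y = ynew;
        double m = std::max(std::abs(y.phi), std::abs(y.dphi));
        if (m > 1e120) {
          y.phi /= m; y.dphi /= m;
          logscale += std::log(m);
        }
        double fac = std::pow(std::max(err / rtol, 1e-10), -0.2);
        h = -std::min(std::fabs(h) * std::min(5.0, 0.9 * fac),
                      0.25 * (1.0 + std::fabs(z)) / (1.0 + 0.0) );
        h = -std::max(std::fabs(h), hmin);
        // cap step so the local scale z and oscillation nu stay resolved
        double cap = 0.5 / (1.0 + std::sqrt(nu) + std::fabs(z) * 0.5);
        if (std::fabs(h) > cap) h = -cap;
      } else {
        h = -std::max(std::fabs(hstep) * std::max(0.2, 0.9 *
                      std::pow(err / rtol, -0.25)), hmin);
      }
    }
    if (std::fabs(z - target) > 1e-9 * std::max(1.0, std::fabs(target))) {
      Rcpp::stop("pcf: failed to land on target %g", target);
    }
    phi_out[ord[idx]].r = y.phi.real();
    phi_out[ord[idx]].i = y.phi.imag();
    dphi_out[ord[idx]].r = y.dphi.real();
    dphi_out[ord[idx]].i = y.dphi.imag();
    ls_out[ord[idx]] = logscale;
  }

  return Rcpp::List::create(Rcpp::Named("phi") = phi_out,
                            Rcpp::Named("dphi") = dphi_out,
                            Rcpp::Named("logscale") = ls_out);
}
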