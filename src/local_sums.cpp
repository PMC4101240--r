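#include <Rcpp.h>
using namespace Rcpp;

// Kernel-window accumulations for the localized region energy.
//
// All three routines walk a (2R+1)^2 stencil of kernel weights `w` centered
// on each requested pixel, clipping the stencil at the image border WITHOUT
// renormalizing: numerator and denominator clip identically, so weighted
// means stay exact. Indices in `rows`/`cols` are 1-based.

// Local interior/exterior fitting means f1/f2.
// hphi = H_eps(phi) precomputed in R so that R and C++ share one Heaviside.
// Denominators at or below `guard` fall back to the plain kernel-weighted
// mean of the image (unconditioned on the contour side).
// [[Rcpp::export]]
List fitting_means_cpp(NumericMatrix I, NumericMatrix hphi, NumericMatrix w,
                       IntegerVector rows, IntegerVector cols, double guard) {
  const int nr = I.nrow(), nc = I.ncol();
  const int R = (w.nrow() - 1) / 2;
  const int n = rows.size();
  NumericVector f1(n), f2(n);
  LogicalVector defined(n);

  for (int p = 0; p < n; ++p) {
    const int r0 = rows[p] - 1, c0 = cols[p] - 1;
    double num1 = 0.0, den1 = 0.0, num2 = 0.0, den2 = 0.0;
    double num0 = 0.0, den0 = 0.0;
    const int rlo = std::max(0, r0 - R), rhi = std::min(nr - 1, r0 + R);
    const int clo = std::max(0, c0 - R), chi = std::min(nc - 1, c0 + R);
    for (int c = clo; c <= chi; ++c) {
      const int wc = c - c0 + R;
      for (int r = rlo; r <= rhi; ++r) {
        const double k = w(r - r0 + R, wc);
        const double h = hphi(r, c);
        const double v = I(r, c);
        num1 += k * h * v;        den1 += k * h;
        num2 += k * (1.0 - h) * v; den2 += k * (1.0 - h);
        num0 += k * v;             den0 += k;
      }
    }
    const double fallback = num0 / den0;
    const bool ok1 = den1 > guard, ok2 = den2 > guard;
    f1[p] = ok1 ? num1 / den1 : fallback;
    f2[p] = ok2 ? num2 / den2 : fallback;
    defined[p] = ok1 && ok2;
  }
  return List::create(_["f1"] = f1, _["f2"] = f2, _["defined"] = defined);
}

// Inner integral of the localized data force at each requested pixel z
// (the variational descent of the localized region energy: the residual is
// taken at the updated pixel z, the fitting means at the neighboring
// contour points x):
//   sum_x K(z,x) * delta_eps(phi(x)) * (l1*(I(z)-f1(x))^2 - l2*(I(z)-f2(x))^2)
// The outer delta_eps(phi(z)) factor is applied by the caller.
// dphi = delta_eps(phi) precomputed in R; f1/f2 are full-image matrices
// (they must be defined on the whole kernel window of every requested
// pixel).
// [[Rcpp::export]]
NumericVector data_force_cpp(NumericMatrix I, NumericMatrix dphi, NumericMatrix w,
                             IntegerVector rows, IntegerVector cols,
                             NumericMatrix f1, NumericMatrix f2,
                             double l1, double l2) {
  const int nr = I.nrow(), nc = I.ncol();
  const int R = (w.nrow() - 1) / 2;
  const int n = rows.size();
  NumericVector out(n);

  for (int p = 0; p < n; ++p) {
    const int r0 = rows[p] - 1, c0 = cols[p] - 1;
    const double Iz = I(r0, c0);
    double s = 0.0;
    const int rlo = std::max(0, r0 - R), rhi = std::min(nr - 1, r0 + R);
    const int clo = std::max(0, c0 - R), chi = std::min(nc - 1, c0 + R);
    for (int c = clo; c <= chi; ++c) {
      const int wc = c - c0 + R;
      for (int r = rlo; r <= rhi; ++r) {
        const double e1 = Iz - f1(r, c), e2 = Iz - f2(r, c);
        s += w(r - r0 + R, wc) * dphi(r, c) * (l1 * e1 * e1 - l2 * e2 * e2);
      }
    }
    out[p] = s;
  }
  return out;
}

// Discretized data term of the total energy (double sum over all pixels):
//   sum_x delta_eps(phi(x)) sum_y K(x,y) [ H(phi(y))*l1*(I(y)-f1(x))^2 +
//                                          (1-H(phi(y)))*l2*(I(y)-f2(x))^2 ]
// f1/f2 are full-image matrices.
// [[Rcpp::export]]
double energy_data_cpp(NumericMatrix I, NumericMatrix hphi, NumericMatrix dphi,
                       NumericMatrix w, NumericMatrix f1, NumericMatrix f2,
                       double l1, double l2) {
  const int nr = I.nrow(), nc = I.ncol();
  const int R = (w.nrow() - 1) / 2;
  double E = 0.0;

  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      const double dx = dphi(r0, c0);
      if (dx == 0.0) continue;
      const double a = f1(r0, c0), b = f2(r0, c0);
      double s = 0.0;
      const int rlo = std::max(0, r0 - R), rhi = std::min(nr - 1, r0 + R);
      const int clo = std::max(0, c0 - R), chi = std::min(nc - 1, c0 + R);
      for (int c = clo; c <= chi; ++c) {
        const int wc = c - c0 + R;
        for (int r = rlo; r <= rhi; ++r) {
          const double v = I(r, c);
          const double h = hphi(r, c);
          const double e1 = v - a, e2 = v - b;
          s += w(r - r0 + R, wc) * (h * l1 * e1 * e1 + (1.0 - h) * l2 * e2 * e2);
        }
      }
      E += dx * s;
    }
  }
  return E;
}
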