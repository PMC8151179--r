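#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Right-hand side of the sectional population balance.
//
// Aggregation uses a precomputed pair list (built in R): for pair k of bins
// (pi, pj) the event rate is coef[k] * n[pi] * n[pj], where coef already
// contains beta0, the kernel matrix entry and the 1/2 factor for pi == pj.
// Each event removes one particle from pi and one from pj and deposits one
// newborn split between bins lo/hi with fractions flo/(1 - flo), the fixed
// pivot weights that conserve number and mass exactly. Pairs whose aggregate
// would exceed the largest representative volume are absent from the list.
//
// Breakage: dn_i += sum_j M[i, j] S_j n_j - S_i n_i with M the
// mass-rescaled redistribution matrix (column j non-zero only for i <= j).
static void pbe_rhs(int nb, const double* n, double* dn, int npairs,
                    const int* pi_, const int* pj_, const double* coef,
                    const int* lo, const int* hi, const double* flo,
                    bool has_brk, const double* svec, const double* redis) {
  for (int i = 0; i < nb; ++i) dn[i] = 0.0;
  for (int k = 0; k < npairs; ++k) {
    double r = coef[k] * n[pi_[k]] * n[pj_[k]];
    dn[pi_[k]] -= r;
    dn[pj_[k]] -= r;
    dn[lo[k]] += r * flo[k];
    dn[hi[k]] += r * (1.0 - flo[k]);
  }
  if (has_brk) {
    for (int j = 0; j < nb; ++j) {
      double sn = svec[j] * n[j];
      if (sn == 0.0) continue;
      dn[j] -= sn;
      const double* col = redis + (size_t)j * nb;
      for (int i = 0; i <= j; ++i) dn[i] += col[i] * sn;
    }
  }
}

// [[Rcpp::export]]
NumericVector pbm_rhs_cpp(NumericVector n, IntegerVector pi_, IntegerVector pj_,
                          NumericVector coef, IntegerVector lo, IntegerVector hi,
                          NumericVector flo, NumericVector svec,
                          NumericMatrix redis, bool has_breakage) {
  int nb = n.size();
  NumericVector dn(nb);
  pbe_rhs(nb, n.begin(), dn.begin(), pi_.size(), pi_.begin(), pj_.begin(),
          coef.begin(), lo.begin(), hi.begin(), flo.begin(), has_breakage,
          svec.begin(), redis.begin());
  return dn;
}

// Adaptive explicit Dormand-Prince 5(4) integration of the PBE over
// [0, t_end]. Error control per component with tolerance atol + rtol * |y|.
// Returns the final state plus step diagnostics; status != 0 flags failure
// (1 = step size underflow, 2 = max step count exceeded).
// [[Rcpp::export]]
List pbm_integrate_cpp(NumericVector n0, double t_end,
                       IntegerVector pi_, IntegerVector pj_, NumericVector coef,
                       IntegerVector lo, IntegerVector hi, NumericVector flo,
                       NumericVector svec, NumericMatrix redis, bool has_breakage,
                       double rtol, double atol, int max_steps) {
  const int nb = n0.size();
  const int np = pi_.size();

  // Dormand-Prince coefficients
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
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                      e3 = 500.0 / 1113 - 7571.0 / 16695,
                      e4 = 125.0 / 192 - 393.0 / 640,
                      e5 = -2187.0 / 6784 + 92097.0 / 339200,
                      e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

  std::vector<double> y(n0.begin(), n0.end()), yt(nb), ynew(nb);
  std::vector<double> k1(nb), k2(nb), k3(nb), k4(nb), k5(nb), k6(nb), k7(nb);

  const double* sv = svec.begin();
  const double* rd = redis.begin();
  const int* pi0 = pi_.begin();
  const int* pj0 = pj_.begin();
  const double* cf = coef.begin();
  const int* lo0 = lo.begin();
  const int* hi0 = hi.begin();
  const double* fl = flo.begin();

  double t = 0.0, h = t_end / 100.0;
  int steps = 0, rejected = 0, status = 0;
  double min_y = 0.0;  // most negative component seen on accepted steps

  pbe_rhs(nb, y.data(), k1.data(), np, pi0, pj0, cf, lo0, hi0, fl,
          has_breakage, sv, rd);

  while (t < t_end) {
    if (steps >= max_steps) { status = 2; break; }
    if (h < 1e-14 * t_end) { status = 1; break; }
    if (t + h > t_end) h = t_end - t;

    for (int i = 0; i < nb; ++i) yt[i] = y[i] + h * a21 * k1[i];
    pbe_rhs(nb, yt.data(), k2.data(), np, pi0, pj0, cf, lo0, hi0, fl,
            has_breakage, sv, rd);
    for (int i = 0; i < nb; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    pbe_rhs(nb, yt.data(), k3.data(), np, pi0, pj0, cf, lo0, hi0, fl,
            has_breakage, sv, rd);
    for (int i = 0; i < nb; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    pbe_rhs(nb, yt.data(), k4.data(), np, pi0, pj0, cf, lo0, hi0, fl,
            has_breakage, sv, rd);
    for (int i = 0; i < nb; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    pbe_rhs(nb, yt.data(), k5.data(), np, pi0, pj0, cf, lo0, hi0, fl,
            has_breakage, sv, rd);
    for (int i = 0; i < nb; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    pbe_rhs(nb, yt.data(), k6.data(), np, pi0, pj0, cf, lo0, hi0, fl,
            has_breakage, sv, rd);
    for (int i = 0; i < nb; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    pbe_rhs(nb, ynew.data(), k7.data(), np, pi0, pj0, cf, lo0, hi0, fl,
            has_breakage, sv, rd);

    // embedded error estimate
    double err = 0.0;
    for (int i = 0; i < nb; ++i) {
      double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / nb);
    ++steps;

    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < nb; ++i) {
        if (ynew[i] < min_y) min_y = ynew[i];
        y[i] = ynew[i];
      }
      std::copy(k7.begin(), k7.end(), k1.begin());  // FSAL
    } else {
      ++rejected;
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
  }

  return List::create(_["state"] = NumericVector(y.begin(), y.end()),
                      _["steps"] = steps, _["rejected"] = rejected,
                      _["status"] = status, _["min_state"] = min_y);
}
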