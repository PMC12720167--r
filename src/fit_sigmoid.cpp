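#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Levenberg-Marquardt least-squares fit of the three-parameter sigmoid
//   f(x) = ymax / (1 + exp(-k * (x - x0)))
// with analytic Jacobian. Written in C++ because the mapping experiments
// refit on the order of 10^6 small per-compartment curves.

static inline double sig01(double a) {
  if (a >= 0.0) {
    double e = std::exp(-std::min(a, 700.0));
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(std::max(a, -700.0));
  return e / (1.0 + e);
}

// Solve symmetric 3x3 system A d = b by cofactor expansion.
static bool solve3(const double A[3][3], const double b[3], double d[3]) {
  double c00 = A[1][1] * A[2][2] - A[1][2] * A[2][1];
  double c01 = A[1][2] * A[2][0] - A[1][0] * A[2][2];
  double c02 = A[1][0] * A[2][1] - A[1][1] * A[2][0];
  double det = A[0][0] * c00 + A[0][1] * c01 + A[0][2] * c02;
  if (!std::isfinite(det) || std::fabs(det) < 1e-300) return false;
  double c10 = A[0][2] * A[2][1] - A[0][1] * A[2][2];
  double c11 = A[0][0] * A[2][2] - A[0][2] * A[2][0];
  double c12 = A[0][1] * A[2][0] - A[0][0] * A[2][1];
  double c20 = A[0][1] * A[1][2] - A[0][2] * A[1][1];
  double c21 = A[0][2] * A[1][0] - A[0][0] * A[1][2];
  double c22 = A[0][0] * A[1][1] - A[0][1] * A[1][0];
  d[0] = (c00 * b[0] + c10 * b[1] + c20 * b[2]) / det;
  d[1] = (c01 * b[0] + c11 * b[1] + c21 * b[2]) / det;
  d[2] = (c02 * b[0] + c12 * b[1] + c22 * b[2]) / det;
  return std::isfinite(d[0]) && std::isfinite(d[1]) && std::isfinite(d[2]);
}

static double sum_sq_resid(const double* x, const double* y, int n,
                           const double p[3]) {
  long double ss = 0.0L;
  for (int i = 0; i < n; ++i) {
    double r = y[i] - p[1] * sig01(p[2] * (x[i] - p[0]));
    ss += (long double)r * r;
  }
  return (double)ss;
}

// out: x0, ymax, slope, r2, status (1 converged, 0 failed/degenerate)
static void fit_one(const double* x, const double* y, int n, double* out) {
  out[0] = NA_REAL; out[1] = NA_REAL; out[2] = NA_REAL;
  out[3] = 0.0; out[4] = 0.0;

  double ymax0 = -INFINITY, xmin = INFINITY, xmax = -INFINITY;
  long double ysum = 0.0L;
  for (int i = 0; i < n; ++i) {
    if (y[i] > ymax0) ymax0 = y[i];
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    ysum += y[i];
  }
  double ybar = (double)(ysum / n);
  long double sstot_l = 0.0L;
  for (int i = 0; i < n; ++i) {
    double d = y[i] - ybar;
    sstot_l += (long double)d * d;
  }
  double sstot = (double)sstot_l;
  // degenerate: constant response (includes all-zero and fully saturated
  // data) or constant predictor — no information for a sigmoid fit
  if (!(sstot > 0.0) || !(ymax0 > 0.0) || !(xmax > xmin)) return;

  // initialization: ymax = max(y); x0 = y-weighted median of x;
  // slope = 4 * ymax / range(x)
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double half = 0.5 * (double)ysum;
  double cum = 0.0, x00 = x[idx[n - 1]];
  for (int i = 0; i < n; ++i) {
    cum += y[idx[i]];
    if (cum >= half) { x00 = x[idx[i]]; break; }
  }
  double p[3] = {x00, ymax0, 4.0 * ymax0 / (xmax - xmin)};
  const double ymax_hi = 2.0 * ymax0;

  double ss = sum_sq_resid(x, y, n, p);
  double lambda = 1e-3;
  bool converged = false;
  const int max_iter = 200;

  for (int iter = 0; iter < max_iter; ++iter) {
    // build normal equations at p
    double A[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    double g[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      double s = sig01(p[2] * (x[i] - p[0]));
      double f = p[1] * s;
      double r = y[i] - f;
      double sp = s * (1.0 - s);
      double J0 = -p[1] * p[2] * sp;          // d f / d x0
      double J1 = s;                          // d f / d ymax
      double J2 = p[1] * (x[i] - p[0]) * sp;  // d f / d slope
      A[0][0] += J0 * J0; A[0][1] += J0 * J1; A[0][2] += J0 * J2;
      A[1][1] += J1 * J1; A[1][2] += J1 * J2; A[2][2] += J2 * J2;
      g[0] += J0 * r; g[1] += J1 * r; g[2] += J2 * r;
    }
    A[1][0] = A[0][1]; A[2][0] = A[0][2]; A[2][1] = A[1][2];

    bool accepted = false;
    while (lambda <= 1e12) {
      double Ad[3][3];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          Ad[a][b] = A[a][b] + (a == b ? lambda * A[a][a] : 0.0);
      // guard fully zero diagonal entries (parameter has no local effect)
      for (int a = 0; a < 3; ++a)
        if (Ad[a][a] <= 0.0) Ad[a][a] = 1e-12;
      double d[3];
      if (!solve3(Ad, g, d)) { lambda *= 10.0; continue; }
      double pt[3] = {p[0] + d[0], p[1] + d[1], p[2] + d[2]};
      if (pt[1] < 1e-12) pt[1] = 1e-12;
      if (pt[1] > ymax_hi) pt[1] = ymax_hi;
      if (pt[2] < 1e-12) pt[2] = 1e-12;
      double ss_t = sum_sq_resid(x, y, n, pt);
      if (std::isfinite(ss_t) && ss_t <= ss) {
        double improved = ss - ss_t;
        p[0] = pt[0]; p[1] = pt[1]; p[2] = pt[2];
        ss = ss_t;
        lambda = std::max(lambda * 0.3, 1e-12);
        accepted = true;
        if (improved <= 1e-12 * (ss + 1e-300)) converged = true;
        if (ss <= 1e-24 * sstot) converged = true;
        break;
      }
      lambda *= 10.0;
    }
    if (!accepted) { converged = true; break; }  // stalled at a minimum
    if (converged) break;
  }

  out[0] = p[0]; out[1] = p[1]; out[2] = p[2];
  if (converged) {
    double r2 = 1.0 - ss / sstot;
    if (r2 < 0.0) r2 = 0.0;
    if (r2 > 1.0) r2 = 1.0;
    out[3] = r2;
    out[4] = 1.0;
  }
}

// [[Rcpp::export(name = ".fit_sigmoid_cpp")]]
List fit_sigmoid_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  double out[5];
  fit_one(REAL(x), REAL(y), n, out);
  return List::create(_["x0"] = out[0], _["ymax"] = out[1],
                      _["slope"] = out[2], _["r2"] = out[3],
                      _["converged"] = out[4] == 1.0);
}

// X: n x K predictor matrix (one column per compartment), y: length-n
// responses. Returns per-compartment parameter estimates and R^2.
// [[Rcpp::export(name = ".fit_sigmoid_batch_cpp")]]
List fit_sigmoid_batch_cpp(NumericMatrix X, NumericVector y) {
  int n = X.nrow(), K = X.ncol();
  NumericVector x0(K), ymax(K), slope(K), r2(K);
  LogicalVector converged(K);
  double out[5];
  const double* yp = REAL(y);
  const double* xp = REAL(X);
  for (int k = 0; k < K; ++k) {
    fit_one(xp + (size_t)k * n, yp, n, out);
    x0[k] = out[0]; ymax[k] = out[1]; slope[k] = out[2];
    r2[k] = out[3]; converged[k] = out[4] == 1.0;
  }
  return List::create(_["x0"] = x0, _["ymax"] = ymax, _["slope"] = slope,
                      _["r2"] = r2, _["converged"] = converged);
}
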