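#include <Rcpp.h>
using namespace Rcpp;

// Gaussian-kernel plug-in MI on pre-transformed (normal-score or raw)
// vectors: densities are evaluated at the sample points themselves (self
// term included). Joint kernel covariance is h^2 * Sigma-hat so the kernel
// adapts to the correlation ridge; marginal bandwidth is h * sd.
// h = bw_factor * n^(-1/6) (Silverman rate, d = 2).

static const double TWO_PI = 6.283185307179586476925286766559;

// mean over i of log( (1/n) sum_l N(x_i - x_l; 0, h^2) )
static double marginal_logmean(const double* x, int n, double h) {
  std::vector<double> f(n, 1.0); // self term: exp(0)
  double inv2h2 = 1.0 / (2.0 * h * h);
  for (int i = 0; i < n; ++i) {
    for (int l = i + 1; l < n; ++l) {
      double d = x[i] - x[l];
      double v = std::exp(-d * d * inv2h2);
      f[i] += v;
      f[l] += v;
    }
  }
  double norm = n * h * std::sqrt(TWO_PI);
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::log(std::max(f[i], 1e-300) / norm);
  return s / n;
}

// mean over i of log plug-in joint density at (x_i, y_i)
static double joint_logmean(const double* x, const double* y, int n,
                            double h) {
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double vx = 0.0, vy = 0.0, cxy = 0.0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - mx, dy = y[i] - my;
    vx += dx * dx; vy += dy * dy; cxy += dx * dy;
  }
  vx /= (n - 1); vy /= (n - 1); cxy /= (n - 1);
  // guard against singular kernel covariance for (near-)duplicated vectors
  double r = cxy / std::sqrt(vx * vy);
  if (r > 0.9999) cxy = 0.9999 * std::sqrt(vx * vy);
  if (r < -0.9999) cxy = -0.9999 * std::sqrt(vx * vy);
  double h2 = h * h;
  double s11 = vx * h2, s22 = vy * h2, s12 = cxy * h2;
  double det = s11 * s22 - s12 * s12;
  double ia = s22 / det, ib = -s12 / det, ic = s11 / det;
  std::vector<double> f(n, 1.0); // self term: exp(0)
  for (int i = 0; i < n; ++i) {
    for (int l = i + 1; l < n; ++l) {
      double dx = x[i] - x[l], dy = y[i] - y[l];
      double q = ia * dx * dx + 2.0 * ib * dx * dy + ic * dy * dy;
      double v = std::exp(-0.5 * q);
      f[i] += v;
      f[l] += v;
    }
  }
  double norm = n * TWO_PI * std::sqrt(det);
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::log(std::max(f[i], 1e-300) / norm);
  return s / n;
}

static double col_sd(const double* x, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  double v = 0.0;
  for (int i = 0; i < n; ++i) v += (x[i] - m) * (x[i] - m);
  return std::sqrt(v / (n - 1));
}

// [[Rcpp::export]]
double cpp_mi_pair(NumericVector x, NumericVector y, double bw_factor) {
  int n = x.size();
  double h = bw_factor * std::pow((double)n, -1.0 / 6.0);
  double sx = col_sd(REAL(x), n), sy = col_sd(REAL(y), n);
  if (sx < 1e-12 || sy < 1e-12) return 0.0;
  double mi = joint_logmean(REAL(x), REAL(y), n, h)
            - marginal_logmean(REAL(x), n, h * sx)
            - marginal_logmean(REAL(y), n, h * sy);
  return mi > 0.0 ? mi : 0.0;
}

// All unordered column pairs of X (samples x features), lexicographic in
// column index: (1,2), (1,3), ..., (p-1,p).
// [[Rcpp::export]]
NumericVector cpp_mi_all_pairs(NumericMatrix X, double bw_factor) {
  int n = X.nrow(), p = X.ncol();
  double h = bw_factor * std::pow((double)n, -1.0 / 6.0);
  std::vector<double> marg(p);
  std::vector<bool> degenerate(p, false);
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double s = col_sd(xj, n);
    if (s < 1e-12) { degenerate[j] = true; marg[j] = 0.0; continue; }
    marg[j] = marginal_logmean(xj, n, h * s);
  }
  NumericVector out((R_xlen_t)p * (p - 1) / 2);
  R_xlen_t k = 0;
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j, ++k) {
      if (degenerate[i] || degenerate[j]) { out[k] = 0.0; continue; }
      double mi = joint_logmean(&X(0, i), &X(0, j), n, h)
                - marg[i] - marg[j];
      out[k] = mi > 0.0 ? mi : 0.0;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
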