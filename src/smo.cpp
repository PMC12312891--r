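#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual:
//   max  sum a_i - 1/2 sum_ij a_i a_j y_i y_j k(x_i, x_j)
//   s.t. 0 <= a_i <= C,  sum a_i y_i = 0
// Platt-style outer loop (all points / non-bound points) with the
// max-|E_i - E_j| second choice plus deterministic fallback scans, and an
// incrementally maintained decision cache. No random choices.

static inline double kernel_eval(const double* xi, const double* xj, int d,
                                 int kernel_type, double gamma) {
  if (kernel_type == 0) { // linear
    double s = 0.0;
    for (int k = 0; k < d; ++k) s += xi[k] * xj[k];
    return s;
  }
  double s = 0.0; // rbf
  for (int k = 0; k < d; ++k) {
    double diff = xi[k] - xj[k];
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

struct SmoState {
  int n;
  double C, tol, b;
  const double* K;   // n x n kernel matrix
  const double* y;
  std::vector<double> alpha, fcache; // fcache = f(x_i) - b

  double error(int i) const { return fcache[i] + b - y[i]; }

  bool take_step(int i, int j) {
    if (i == j) return false;
    double Ei = error(i), Ej = error(j);
    double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (L >= H) return false;
    double kii = K[(size_t)i * n + i], kjj = K[(size_t)j * n + j],
           kij = K[(size_t)i * n + j];
    double eta = 2.0 * kij - kii - kjj;
    if (eta >= -1e-12) return false;
    double aj = aj_old - y[j] * (Ei - Ej) / eta;
    if (aj > H) aj = H; else if (aj < L) aj = L;
    if (std::fabs(aj - aj_old) < 1e-10 * (aj + aj_old + 1e-8)) return false;
    double ai = ai_old + y[i] * y[j] * (aj_old - aj);

    double b1 = b - Ei - y[i] * (ai - ai_old) * kii - y[j] * (aj - aj_old) * kij;
    double b2 = b - Ej - y[i] * (ai - ai_old) * kij - y[j] * (aj - aj_old) * kjj;
    if (ai > 0 && ai < C) b = b1;
    else if (aj > 0 && aj < C) b = b2;
    else b = 0.5 * (b1 + b2);

    double di = y[i] * (ai - ai_old), dj = y[j] * (aj - aj_old);
    const double* Ki = &K[(size_t)i * n];
    const double* Kj = &K[(size_t)j * n];
    for (int t = 0; t < n; ++t) fcache[t] += di * Ki[t] + dj * Kj[t];
    alpha[i] = ai; alpha[j] = aj;
    return true;
  }

  bool examine(int i) {
    double Ei = error(i);
    double r = y[i] * Ei;
    if (!((r < -tol && alpha[i] < C) || (r > tol && alpha[i] > 0)))
      return false;
    // 1. best-gap partner among non-bound points
    int best_j = -1; double best = -1.0;
    for (int t = 0; t < n; ++t) {
      if (alpha[t] <= 0 || alpha[t] >= C) continue;
      double gap = std::fabs(Ei - error(t));
      if (gap > best) { best = gap; best_j = t; }
    }
    if (best_j >= 0 && take_step(i, best_j)) return true;
    // 2. sweep non-bound points
    for (int t = 0; t < n; ++t)
      if (alpha[t] > 0 && alpha[t] < C && take_step(i, t)) return true;
    // 3. sweep everything
    for (int t = 0; t < n; ++t)
      if (take_step(i, t)) return true;
    return false;
  }
};

// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix X, NumericVector y, double C,
               int kernel_type, double gamma,
               double tol, int max_passes, int max_iter) {
  const int n = X.nrow(), d = X.ncol();
  if (n != y.size()) stop("X and y sizes differ");
  if ((double)n * (double)n > 4.9e7)
    stop("training set too large for a dense kernel matrix; subsample first");

  std::vector<double> xr((size_t)n * d); // row-major for cache locality
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) xr[(size_t)i * d + k] = X(i, k);

  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double v = kernel_eval(&xr[(size_t)i * d], &xr[(size_t)j * d], d,
                             kernel_type, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  SmoState st;
  st.n = n; st.C = C; st.tol = tol; st.b = 0.0;
  st.K = K.data(); st.y = REAL(y);
  st.alpha.assign(n, 0.0); st.fcache.assign(n, 0.0);

  bool examine_all = true;
  int iter = 0, quiet = 0;
  while (iter < max_iter && quiet < max_passes) {
    int num_changed = 0;
    for (int i = 0; i < n; ++i) {
      if (!examine_all && (st.alpha[i] <= 0 || st.alpha[i] >= C)) continue;
      if (st.examine(i)) ++num_changed;
    }
    ++iter;
    if (num_changed == 0) {
      if (examine_all) ++quiet; else examine_all = true;
    } else {
      examine_all = false;
      quiet = 0;
    }
  }

  return List::create(_["alpha"] = NumericVector(st.alpha.begin(), st.alpha.end()),
                      _["b"] = st.b,
                      _["iterations"] = iter,
                      _["converged"] = (iter < max_iter));
}
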