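#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Soft-margin binary SVM trained by sequential minimal optimization (SMO),
// Platt-style with an error cache and deterministic working-set selection
// (second index chosen to maximize |E1 - E2|), so repeated fits on the same
// data are bit-identical. Kernel: 0 = linear, 1 = RBF with parameter gamma.
// Per-sample box constraints Cvec allow class weighting.

static inline double kern_ij(const NumericMatrix &X, int i, int j,
                             int kernel, double gamma) {
  const int d = X.ncol();
  double s = 0.0;
  if (kernel == 0) {
    for (int k = 0; k < d; ++k) s += X(i, k) * X(j, k);
    return s;
  }
  for (int k = 0; k < d; ++k) {
    const double diff = X(i, k) - X(j, k);
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix X, NumericVector y, NumericVector Cvec,
               int kernel, double gamma, double tol, int max_passes) {
  const int n = X.nrow();
  std::vector<double> alpha(n, 0.0), err(n);
  double b = 0.0;

  // Gram matrix: n is kept modest by callers (sector signatures, 5-D scores)
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      K(i, j) = K(j, i) = kern_ij(X, i, j, kernel, gamma);

  for (int i = 0; i < n; ++i) err[i] = -y[i]; // f(x)=0 initially

  auto take_step = [&](int i1, int i2) -> bool {
    if (i1 == i2) return false;
    const double a1 = alpha[i1], a2 = alpha[i2];
    const double y1 = y[i1], y2 = y[i2];
    const double E1 = err[i1], E2 = err[i2];
    const double s = y1 * y2;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a2 - a1);
      H = std::min(Cvec[i2], Cvec[i1] + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - Cvec[i1]);
      H = std::min(Cvec[i2], a1 + a2);
    }
    if (H - L < 1e-12) return false;
    const double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    const double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > 1e-12) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      // degenerate curvature: evaluate objective at both clip ends
      const double f1 = y1 * (E1 + b) - a1 * k11 - s * a2 * k12;
      const double f2 = y2 * (E2 + b) - s * a1 * k12 - a2 * k22;
      const double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      const double objL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                          0.5 * L * L * k22 + s * L * L1 * k12;
      const double objH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                          0.5 * H * H * k22 + s * H * H1 * k12;
      if (objL < objH - 1e-12) a2new = L;
      else if (objL > objH + 1e-12) a2new = H;
      else a2new = a2;
    }
    if (std::fabs(a2new - a2) < 1e-12 * (a2new + a2 + 1e-12)) return false;
    const double a1new = a1 + s * (a2 - a2new);

    const double b1 = b - E1 - y1 * (a1new - a1) * k11 - y2 * (a2new - a2) * k12;
    const double b2 = b - E2 - y1 * (a1new - a1) * k12 - y2 * (a2new - a2) * k22;
    double bnew;
    const bool i1_in = a1new > 1e-12 && a1new < Cvec[i1] - 1e-12;
    const bool i2_in = a2new > 1e-12 && a2new < Cvec[i2] - 1e-12;
    if (i1_in) bnew = b1;
    else if (i2_in) bnew = b2;
    else bnew = 0.5 * (b1 + b2);

    const double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2), db = bnew - b;
    for (int k = 0; k < n; ++k)
      err[k] += d1 * K(i1, k) + d2 * K(i2, k) + db;
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    b = bnew;
    return true;
  };

  auto examine = [&](int i2) -> int {
    const double y2 = y[i2], a2 = alpha[i2], E2 = err[i2];
    const double r2 = E2 * y2;
    if ((r2 < -tol && a2 < Cvec[i2] - 1e-12) || (r2 > tol && a2 > 1e-12)) {
      // heuristic 1: maximize |E1 - E2| over non-bound multipliers
      int best = -1;
      double bestgap = -1.0;
      for (int k = 0; k < n; ++k) {
        if (alpha[k] > 1e-12 && alpha[k] < Cvec[k] - 1e-12) {
          const double gap = std::fabs(err[k] - E2);
          if (gap > bestgap) { bestgap = gap; best = k; }
        }
      }
      if (best >= 0 && take_step(best, i2)) return 1;
      // heuristic 2: sweep non-bound, then all (deterministic order)
      for (int k = 0; k < n; ++k)
        if (alpha[k] > 1e-12 && alpha[k] < Cvec[k] - 1e-12 && take_step(k, i2))
          return 1;
      for (int k = 0; k < n; ++k)
        if (take_step(k, i2)) return 1;
    }
    return 0;
  };

  int passes = 0, num_changed = 0;
  bool examine_all = true;
  while ((num_changed > 0 || examine_all) && passes < max_passes) {
    num_changed = 0;
    if (examine_all) {
      for (int k = 0; k < n; ++k) num_changed += examine(k);
    } else {
      for (int k = 0; k < n; ++k)
        if (alpha[k] > 1e-12 && alpha[k] < Cvec[k] - 1e-12)
          num_changed += examine(k);
    }
    if (examine_all) examine_all = false;
    else if (num_changed == 0) examine_all = true;
    ++passes;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["passes"] = passes);
}

// Decision values f(x) = sum_i alpha_i y_i K(x_i, x) + b for rows of Xnew.
// [[Rcpp::export(name = ".smo_decision")]]
NumericVector smo_decision(NumericMatrix Xsv, NumericVector coef, double b,
                           NumericMatrix Xnew, int kernel, double gamma) {
  const int m = Xnew.nrow(), nsv = Xsv.nrow(), d = Xsv.ncol();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double f = b;
    for (int i = 0; i < nsv; ++i) {
      double s = 0.0;
      if (kernel == 0) {
        for (int k = 0; k < d; ++k) s += Xsv(i, k) * Xnew(j, k);
        f += coef[i] * s;
      } else {
        for (int k = 0; k < d; ++k) {
          const double diff = Xsv(i, k) - Xnew(j, k);
          s += diff * diff;
        }
        f += coef[i] * std::exp(-gamma * s);
      }
    }
    out[j] = f;
  }
  return out;
}
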