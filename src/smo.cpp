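#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual:
//   max_a  sum a_n - 1/2 sum_{m,n} a_m a_n y_m y_n K(m,n)
//   s.t.   0 <= a_n <= C,  sum a_n y_n = 0.
// Platt's algorithm over a precomputed kernel matrix, with an error cache
// and deterministic working-pair selection (max |E1 - E2| among non-bound
// points, then a fixed-order sweep). Pairwise updates preserve the equality
// constraint exactly. The decision value convention is u = s(x) - b.

namespace {

struct SMO {
  const NumericMatrix& K;
  const NumericVector& y;
  double C, tol, eps;
  int n;
  std::vector<double> alpha, E; // E_i = u_i - y_i
  double b;
  long steps, maxSteps;

  SMO(const NumericMatrix& K_, const NumericVector& y_, double C_,
      double tol_, long maxSteps_)
      : K(K_), y(y_), C(C_), tol(tol_), eps(1e-12), n(y_.size()),
        alpha(n, 0.0), E(n), b(0.0), steps(0), maxSteps(maxSteps_) {
    for (int i = 0; i < n; ++i) E[i] = -y[i]; // u = 0 initially
  }

  bool takeStep(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2];
    double E1 = E[i1], E2 = E[i2];
    double s = y1 * y2;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a2 - a1);
      H = std::min(C, C + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - C);
      H = std::min(C, a1 + a2);
    }
    if (H - L < eps) return false;
    double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > eps) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      // objective is linear (or degenerate) along the segment: test ends
      double f1 = y1 * (E1 + b) - a1 * k11 - s * a2 * k12;
      double f2 = y2 * (E2 + b) - a2 * k22 - s * a1 * k12;
      double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      double Lobj = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                    0.5 * L * L * k22 + s * L * L1 * k12;
      double Hobj = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                    0.5 * H * H * k22 + s * H * H1 * k12;
      if (Lobj < Hobj - eps) a2new = L;
      else if (Lobj > Hobj + eps) a2new = H;
      else a2new = a2;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    double a1new = a1 + s * (a2 - a2new);
    if (a1new < 0) { a2new += s * a1new; a1new = 0; }
    else if (a1new > C) { a2new += s * (a1new - C); a1new = C; }

    // bias update (Platt): keep E consistent with u = s(x) - b
    double b1 = E1 + y1 * (a1new - a1) * k11 + y2 * (a2new - a2) * k12 + b;
    double b2 = E2 + y1 * (a1new - a1) * k12 + y2 * (a2new - a2) * k22 + b;
    double bnew;
    bool free1 = a1new > eps && a1new < C - eps;
    bool free2 = a2new > eps && a2new < C - eps;
    if (free1) bnew = b1;
    else if (free2) bnew = b2;
    else bnew = 0.5 * (b1 + b2);

    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2);
    for (int i = 0; i < n; ++i)
      E[i] += d1 * K(i1, i) + d2 * K(i2, i) - (bnew - b);
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    b = bnew;
    ++steps;
    return true;
  }

  bool examine(int i2) {
    double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    double r2 = E2 * y2;
    if ((r2 < -tol && a2 < C - eps) || (r2 > tol && a2 > eps)) {
      // heuristic 1: maximize |E1 - E2| over non-bound points
      int best = -1;
      double gap = 0.0;
      for (int i = 0; i < n; ++i) {
        if (alpha[i] > eps && alpha[i] < C - eps) {
          double g = std::fabs(E[i] - E2);
          if (g > gap) { gap = g; best = i; }
        }
      }
      if (best >= 0 && takeStep(best, i2)) return true;
      // heuristic 2: sweep non-bound, then all, in fixed order
      for (int i = 0; i < n; ++i)
        if (alpha[i] > eps && alpha[i] < C - eps && takeStep(i, i2))
          return true;
      for (int i = 0; i < n; ++i)
        if (takeStep(i, i2)) return true;
    }
    return false;
  }

  void solve() {
    int changed = 0;
    bool examineAll = true;
    while ((changed > 0 || examineAll) && steps < maxSteps) {
      changed = 0;
      if (examineAll) {
        for (int i = 0; i < n && steps < maxSteps; ++i)
          changed += examine(i);
      } else {
        for (int i = 0; i < n && steps < maxSteps; ++i)
          if (alpha[i] > eps && alpha[i] < C - eps)
            changed += examine(i);
      }
      if (examineAll) examineAll = false;
      else if (changed == 0) examineAll = true;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".smoSolve")]]
List smoSolve(NumericMatrix K, NumericVector y, double C, double tol,
              long maxSteps = 2000000) {
  if (K.nrow() != K.ncol() || K.nrow() != y.size())
    stop("kernel matrix / label size mismatch");
  SMO s(K, y, C, tol, maxSteps);
  s.solve();
  return List::create(
      _["alpha"] = NumericVector(s.alpha.begin(), s.alpha.end()),
      _["b"] = s.b,
      _["steps"] = (double)s.steps,
      _["converged"] = s.steps < maxSteps);
}
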