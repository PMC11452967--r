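#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact minimizer of
//   0.5*||theta - b||^2 + 0.5*||w - v||^2 + lambda * sum_t |theta_t|
//   subject to ||w||_inf <= nu * max_t |theta_t|
// for one feature row (b in R^k, v in R^h). The problem reduces to a
// one-dimensional convex piecewise-quadratic minimization over
// M = max_t |theta_t|: for fixed M every theta coordinate is the
// soft-threshold value capped at M (with the cheapest coordinate pushed up
// to M when M exceeds the unconstrained maximum), and every w coordinate is
// v clamped to [-nu*M, nu*M]. The derivative in M is piecewise linear and
// non-decreasing, so the minimizer is found by an ascending sweep over the
// O(h + k) breakpoints (sorted), i.e. O((h + k) log(h + k)) per row.
static void hier_prox_row(const double *b, int k, const double *v, int h,
                          double lambda, double nu, double *theta_out,
                          double *w_out) {
  // Unconstrained limits.
  if (!R_finite(nu)) {
    for (int t = 0; t < k; ++t) {
      double a = std::fabs(b[t]) - lambda;
      theta_out[t] = a > 0 ? (b[t] > 0 ? a : -a) : 0.0;
    }
    std::copy(v, v + h, w_out);
    return;
  }
  if (nu <= 0.0) {
    for (int t = 0; t < k; ++t) {
      double a = std::fabs(b[t]) - lambda;
      theta_out[t] = a > 0 ? (b[t] > 0 ? a : -a) : 0.0;
    }
    std::fill(w_out, w_out + h, 0.0);
    return;
  }

  // Soft-threshold magnitudes and the push coordinate (largest |b|).
  std::vector<double> s(k);
  double m0 = 0.0, babs_max = 0.0;
  int tstar = 0;
  for (int t = 0; t < k; ++t) {
    double ab = std::fabs(b[t]);
    s[t] = ab > lambda ? ab - lambda : 0.0;
    if (s[t] > m0) m0 = s[t];
    if (ab > babs_max) { babs_max = ab; tstar = t; }
  }

  // Events where the derivative slope/offset changes (ascending M):
  //  - M = s_t      : theta coordinate t stops being capped at M
  //  - M = m0       : the push term switches on
  //  - M = |v_j|/nu : w coordinate j stops being clamped
  // phi'(M) = A*M + C on each interval between consecutive events, with
  //  A = #capped + nu^2 * #clamped + (M > m0)
  //  C = sum_capped (lambda - |b_t|) - nu * sum_clamped |v_j| + (M > m0)(lambda - |b*|)
  struct Event { double m; double dA; double dC; };
  std::vector<Event> ev;
  ev.reserve(k + h + 1);
  double A = 0.0, C = 0.0;
  for (int t = 0; t < k; ++t) {
    if (s[t] > 0.0) {  // capped for M < s_t
      A += 1.0;
      C += lambda - std::fabs(b[t]);
      ev.push_back({s[t], -1.0, -(lambda - std::fabs(b[t]))});
    }
  }
  for (int j = 0; j < h; ++j) {
    double av = std::fabs(v[j]);
    if (av > 0.0) {  // clamped for M < |v_j|/nu
      A += nu * nu;
      C += -nu * av;
      ev.push_back({av / nu, -nu * nu, nu * av});
    }
  }
  // Push term applies for M > m0 (at m0 the derivative is continuous when
  // m0 > 0, and jumps by the non-negative lambda - |b*| when m0 == 0).
  ev.push_back({m0, 1.0, lambda - babs_max});

  std::sort(ev.begin(), ev.end(),
            [](const Event &a, const Event &b) { return a.m < b.m; });

  double M = 0.0;
  double lo = 0.0;
  std::size_t i = 0;
  bool found = false;
  while (true) {
    // apply events at lo
    while (i < ev.size() && ev[i].m <= lo + 0.0) {
      A += ev[i].dA;
      C += ev[i].dC;
      ++i;
    }
    double hi = (i < ev.size()) ? ev[i].m : R_PosInf;
    double dlo = A * lo + C;
    if (dlo >= 0.0) { M = lo; found = true; break; }
    if (A > 0.0) {
      double cand = -C / A;
      if (cand <= hi) { M = cand; found = true; break; }
    }
    if (!R_finite(hi)) break;  // derivative stays negative: unbounded below
    lo = hi;                   // cannot happen for this objective
  }
  if (!found) M = lo;
  if (M < 0.0) M = 0.0;

  // Reconstruct theta and w from the optimal M.
  if (M <= 0.0) {
    std::fill(theta_out, theta_out + k, 0.0);
    std::fill(w_out, w_out + h, 0.0);
    return;
  }
  for (int t = 0; t < k; ++t) {
    double mag = s[t] < M ? s[t] : M;
    theta_out[t] = b[t] >= 0 ? mag : -mag;
  }
  if (M > m0) theta_out[tstar] = b[tstar] >= 0 ? M : -M;
  double lim = nu * M;
  for (int j = 0; j < h; ++j) {
    w_out[j] = std::max(-lim, std::min(lim, v[j]));
  }
}

// Apply the hierarchical proximal operator to every feature row of the skip
// matrix Theta (p x k) and first hidden layer W1 (p x h). Rows where
// active == FALSE are forced to zero (used to freeze dropped features along
// the regularization path).
// [[Rcpp::export]]
List hier_prox_matrix_cpp(NumericMatrix Theta, NumericMatrix W1, double lambda,
                          double nu, LogicalVector active) {
  int p = Theta.nrow(), k = Theta.ncol(), h = W1.ncol();
  if (W1.nrow() != p) stop("Theta and W1 must have the same number of rows");
  if (lambda < 0 || ISNAN(lambda)) stop("lambda must be >= 0");
  if (nu < 0 || ISNAN(nu)) stop("nu must be >= 0");
  NumericMatrix Tout(p, k), Wout(p, h);
  std::vector<double> b(k), v(h), tb(k), wb(h);
  for (int i = 0; i < p; ++i) {
    if (active.size() == p && !active[i]) {
      for (int t = 0; t < k; ++t) Tout(i, t) = 0.0;
      for (int j = 0; j < h; ++j) Wout(i, j) = 0.0;
      continue;
    }
    for (int t = 0; t < k; ++t) b[t] = Theta(i, t);
    for (int j = 0; j < h; ++j) v[j] = W1(i, j);
    hier_prox_row(b.data(), k, v.data(), h, lambda, nu, tb.data(), wb.data());
    for (int t = 0; t < k; ++t) Tout(i, t) = tb[t];
    for (int j = 0; j < h; ++j) Wout(i, j) = wb[j];
  }
  return List::create(_["theta"] = Tout, _["w"] = Wout);
}
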