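#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Sequential minimal optimization for the epsilon-SVR dual, following the
// standard 2n-variable formulation with maximal-violating-pair working-set
// selection (second-order heuristic). Variables z[0..n-1] are alpha,
// z[n..2n-1] are alpha*, with "labels" s = +1 / -1; the quadratic form is
// Q(t,u) = s_t * s_u * K(t mod n, u mod n) and the linear term
// p_t = eps - s_t * y_{t mod n}. The solution vector beta = alpha - alpha*
// and offset b give f(x) = sum_i beta_i K(x_i, x) + b.

static const double TAU = 1e-12;

// [[Rcpp::export(name = ".svr_smo")]]
List svr_smo(NumericMatrix K, NumericVector y, double C, double eps_tube,
             double tol, int max_iter) {
  const int n = K.nrow();
  const int l = 2 * n;
  std::vector<double> z(l, 0.0), G(l), s(l), QD(l);
  for (int t = 0; t < l; ++t) {
    int i = t % n;
    s[t] = (t < n) ? 1.0 : -1.0;
    G[t] = eps_tube - s[t] * y[i];
    QD[t] = K(i, i);
  }
  int iter = 0;
  while (iter < max_iter) {
    // working-set selection
    double Gmax = -INFINITY, Gmax2 = -INFINITY;
    int i_sel = -1;
    for (int t = 0; t < l; ++t) {
      if (s[t] > 0) {
        if (z[t] < C && -G[t] > Gmax) { Gmax = -G[t]; i_sel = t; }
      } else {
        if (z[t] > 0 && G[t] > Gmax) { Gmax = G[t]; i_sel = t; }
      }
    }
    int j_sel = -1;
    double obj_min = INFINITY;
    const int ii = (i_sel >= 0) ? i_sel % n : 0;
    for (int t = 0; t < l; ++t) {
      bool in_low = (s[t] > 0) ? (z[t] > 0) : (z[t] < C);
      if (!in_low) continue;
      double yG = s[t] * G[t];
      if (yG > Gmax2) Gmax2 = yG;
      if (i_sel < 0) continue;
      double b_t = Gmax + yG;  // violation margin
      if (b_t > 0) {
        // curvature along the feasible direction: K_ii + K_tt - 2 K_it
        double a_t = QD[i_sel] + QD[t] - 2.0 * K(ii, t % n);
        if (a_t <= 0) a_t = TAU;
        double objv = -(b_t * b_t) / a_t;
        if (objv < obj_min) { obj_min = objv; j_sel = t; }
      }
    }
    if (i_sel < 0 || j_sel < 0 || Gmax + Gmax2 < tol) break;

    const int i = i_sel, j = j_sel;
    const int im = i % n, jm = j % n;
    const double Qij = s[i] * s[j] * K(im, jm);
    double old_zi = z[i], old_zj = z[j];

    if (s[i] != s[j]) {
      double quad = QD[i] + QD[j] + 2.0 * Qij;
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = z[i] - z[j];
      z[i] += delta; z[j] += delta;
      if (diff > 0) {
        if (z[j] < 0) { z[j] = 0; z[i] = diff; }
      } else {
        if (z[i] < 0) { z[i] = 0; z[j] = -diff; }
      }
      if (diff > 0) {
        if (z[i] > C) { z[i] = C; z[j] = C - diff; }
      } else {
        if (z[j] > C) { z[j] = C; z[i] = C + diff; }
      }
    } else {
      double quad = QD[i] + QD[j] - 2.0 * Qij;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = z[i] + z[j];
      z[i] -= delta; z[j] += delta;
      if (sum > C) {
        if (z[i] > C) { z[i] = C; z[j] = sum - C; }
      } else {
        if (z[j] < 0) { z[j] = 0; z[i] = sum; }
      }
      if (sum > C) {
        if (z[j] > C) { z[j] = C; z[i] = sum - C; }
      } else {
        if (z[i] < 0) { z[i] = 0; z[j] = sum; }
      }
    }

    double dzi = z[i] - old_zi, dzj = z[j] - old_zj;
    if (dzi == 0.0 && dzj == 0.0) { ++iter; continue; }
    for (int t = 0; t < l; ++t) {
      int tm = t % n;
      G[t] += s[t] * (s[i] * K(tm, im) * dzi + s[j] * K(tm, jm) * dzj);
    }
    ++iter;
  }

  // offset from the KKT conditions (free variables, else midpoint of bounds)
  double ub = INFINITY, lb = -INFINITY, sum_free = 0.0;
  int nr_free = 0;
  for (int t = 0; t < l; ++t) {
    double yG = s[t] * G[t];
    if (z[t] >= C) {
      if (s[t] < 0) { if (yG < ub) ub = yG; } else { if (yG > lb) lb = yG; }
    } else if (z[t] <= 0) {
      if (s[t] > 0) { if (yG < ub) ub = yG; } else { if (yG > lb) lb = yG; }
    } else {
      ++nr_free; sum_free += yG;
    }
  }
  double rho = (nr_free > 0) ? sum_free / nr_free : (ub + lb) / 2.0;

  NumericVector beta(n);
  for (int i = 0; i < n; ++i) beta[i] = z[i] - z[i + n];
  return List::create(_["beta"] = beta, _["b"] = -rho,
                      _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
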