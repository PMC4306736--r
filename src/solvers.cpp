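// Dual coordinate-descent solvers for the linear ranking SVM, the linear
// soft-margin SVC, and the Crammer-Singer multi-class SVM, all without an
// intercept term. Instances are columns of a dgCMatrix. Convergence is
// certified by the duality gap, so a run that reports `converged = TRUE`
// is tol-optimal for the convex objective it minimizes.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline uint32_t xorshift32(uint32_t &s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

// Fisher-Yates shuffle driven by a private xorshift stream so that fitted
// models are reproducible across platforms independently of R's RNG.
static void shuffle_idx(std::vector<int> &idx, uint32_t &state) {
  for (int t = (int)idx.size() - 1; t > 0; --t) {
    int u = (int)(xorshift32(state) % (uint32_t)(t + 1));
    std::swap(idx[t], idx[u]);
  }
}

struct SparseCols {
  const int *p;
  const int *i;
  const double *x;
  int ncol, nrow;
};

static inline double col_dot_w(const SparseCols &X, int col,
                               const std::vector<double> &w) {
  double acc = 0.0;
  for (int t = X.p[col]; t < X.p[col + 1]; ++t) acc += w[X.i[t]] * X.x[t];
  return acc;
}

static inline void w_add_col(std::vector<double> &w, const SparseCols &X,
                             int col, double coef) {
  for (int t = X.p[col]; t < X.p[col + 1]; ++t) w[X.i[t]] += coef * X.x[t];
}

static inline double col_norm2(const SparseCols &X, int col) {
  double acc = 0.0;
  for (int t = X.p[col]; t < X.p[col + 1]; ++t) acc += X.x[t] * X.x[t];
  return acc;
}

// dot of two columns; row indices within a dgCMatrix column are sorted
static double col_cross(const SparseCols &X, int a, int b) {
  int ta = X.p[a], tb = X.p[b];
  double acc = 0.0;
  while (ta < X.p[a + 1] && tb < X.p[b + 1]) {
    if (X.i[ta] == X.i[tb]) { acc += X.x[ta] * X.x[tb]; ++ta; ++tb; }
    else if (X.i[ta] < X.i[tb]) ++ta;
    else ++tb;
  }
  return acc;
}

static SparseCols wrap_dgc(const S4 &M, IntegerVector &pi, IntegerVector &ii,
                           NumericVector &xi) {
  pi = M.slot("p"); ii = M.slot("i"); xi = M.slot("x");
  IntegerVector dim = M.slot("Dim");
  SparseCols X;
  X.p = INTEGER(pi); X.i = INTEGER(ii); X.x = REAL(xi);
  X.nrow = dim[0]; X.ncol = dim[1];
  return X;
}

// Ranking SVM with k-partite pairwise hinge loss.
//
// margin variant: J(w) = 0.5||w||^2 + (C/W) sum_P max(0, (s_i-s_j) - w'z_p)
// slack  variant: J(w) = 0.5||w||^2 + (C/W) sum_P (s_i-s_j) max(0, 1 - w'z_p)
// with z_p = x_i - x_j and W = sum_P (s_i - s_j).
//
// Both collapse to per-pair (margin mu_p, box cap c_p) hinges; the dual is a
// box-constrained QP solved by coordinate descent over pairs.
// [[Rcpp::export(name = ".ranksvm_dual_cd")]]
List ranksvm_dual_cd(S4 Xs4, IntegerVector s, double C, std::string variant,
                     double tol, int max_iter, int seed) {
  IntegerVector pslot, islot; NumericVector xslot;
  SparseCols X = wrap_dgc(Xs4, pslot, islot, xslot);
  const int l = X.ncol, dim = X.nrow;
  if (s.size() != l) stop("scores length must equal ncol(X)");

  // group instances by distinct score, descending
  std::vector<int> uniq(s.begin(), s.end());
  std::sort(uniq.begin(), uniq.end(), std::greater<int>());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  const int R = (int)uniq.size();
  if (R < 2) stop("all rank scores are equal; the pair set is empty");
  std::vector<std::vector<int> > groups(R);
  for (int k = 0; k < l; ++k) {
    int g = (int)(std::lower_bound(uniq.begin(), uniq.end(), s[k],
                                   std::greater<int>()) - uniq.begin());
    groups[g].push_back(k);
  }

  std::vector<int> pi, pj;
  std::vector<double> mu, cap;
  double W = 0.0;
  for (int a = 0; a < R; ++a)
    for (int b = a + 1; b < R; ++b) {
      double sd = (double)(uniq[a] - uniq[b]);
      for (size_t u = 0; u < groups[a].size(); ++u)
        for (size_t v = 0; v < groups[b].size(); ++v) {
          pi.push_back(groups[a][u]);
          pj.push_back(groups[b][v]);
          mu.push_back(variant == "slack" ? 1.0 : sd);
          cap.push_back(sd);  // filled with C-scaled value below
          W += sd;
        }
    }
  const int P = (int)pi.size();
  for (int q = 0; q < P; ++q)
    cap[q] = (variant == "slack") ? C * cap[q] / W : C / W;

  std::vector<double> nrm2(l);
  for (int k = 0; k < l; ++k) nrm2[k] = col_norm2(X, k);
  std::vector<double> Q(P), alpha(P, 0.0);
  std::vector<double> w((size_t)dim, 0.0);
  for (int q = 0; q < P; ++q) {
    Q[q] = nrm2[pi[q]] + nrm2[pj[q]] - 2.0 * col_cross(X, pi[q], pj[q]);
    if (Q[q] <= 1e-12) alpha[q] = cap[q];  // z_p = 0: constant loss, cap dual
  }

  std::vector<int> order(P);
  for (int q = 0; q < P; ++q) order[q] = q;
  uint32_t rng = (uint32_t)seed * 2654435761u + 88172645u;

  std::vector<double> f(l), trace;
  double primal = 0.0, dual = 0.0, gap = R_PosInf;
  bool converged = false;
  int pass = 0;
  for (pass = 1; pass <= max_iter; ++pass) {
    shuffle_idx(order, rng);
    for (int t = 0; t < P; ++t) {
      int q = order[t];
      if (Q[q] <= 1e-12) continue;
      double wz = col_dot_w(X, pi[q], w) - col_dot_w(X, pj[q], w);
      double G = wz - mu[q];
      double a_old = alpha[q];
      double PG = G;
      if (a_old <= 0.0 && G > 0.0) PG = 0.0;
      if (a_old >= cap[q] && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > 1e-12) {
        double a_new = std::min(cap[q], std::max(0.0, a_old - G / Q[q]));
        double delta = a_new - a_old;
        if (delta != 0.0) {
          w_add_col(w, X, pi[q], delta);
          w_add_col(w, X, pj[q], -delta);
          alpha[q] = a_new;
        }
      }
    }
    // duality gap via cached predictions
    for (int k = 0; k < l; ++k) f[k] = col_dot_w(X, k, w);
    double w2 = 0.0;
    for (int r = 0; r < dim; ++r) w2 += w[r] * w[r];
    double hinge = 0.0, lin = 0.0;
    for (int q = 0; q < P; ++q) {
      double h = mu[q] - (f[pi[q]] - f[pj[q]]);
      if (h > 0.0) hinge += cap[q] * h;
      lin += alpha[q] * mu[q];
    }
    primal = 0.5 * w2 + hinge;
    dual = lin - 0.5 * w2;
    gap = primal - dual;
    trace.push_back(primal);
    if (gap <= tol * std::max(1.0, std::fabs(primal))) { converged = true; break; }
  }
  if (pass > max_iter) pass = max_iter;

  double hinge_total = primal;  // recompute loss term L(w) on exit
  {
    double w2 = 0.0;
    for (int r = 0; r < dim; ++r) w2 += w[r] * w[r];
    hinge_total = primal - 0.5 * w2;
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["objective"] = primal,
                      _["loss"] = (C > 0 ? hinge_total / C : 0.0),
                      _["gap"] = gap,
                      _["n_pairs"] = P,
                      _["pair_weight_total"] = W,
                      _["iterations"] = pass,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged);
}

// Linear soft-margin SVC (L1 hinge, no intercept):
// J(w) = 0.5||w||^2 + C sum_i max(0, 1 - y_i w'x_i)
// [[Rcpp::export(name = ".svc_dual_cd")]]
List svc_dual_cd(S4 Xs4, NumericVector y, double C, double tol, int max_iter,
                 int seed) {
  IntegerVector pslot, islot; NumericVector xslot;
  SparseCols X = wrap_dgc(Xs4, pslot, islot, xslot);
  const int l = X.ncol, dim = X.nrow;
  if (y.size() != l) stop("labels length must equal ncol(X)");

  std::vector<double> nrm2(l), alpha(l, 0.0), w((size_t)dim, 0.0);
  for (int k = 0; k < l; ++k) {
    nrm2[k] = col_norm2(X, k);
    if (nrm2[k] <= 1e-12) alpha[k] = C;
  }
  std::vector<int> order(l);
  for (int k = 0; k < l; ++k) order[k] = k;
  uint32_t rng = (uint32_t)seed * 2654435761u + 362436069u;

  std::vector<double> trace;
  double primal = 0.0, gap = R_PosInf;
  bool converged = false;
  int pass = 0;
  for (pass = 1; pass <= max_iter; ++pass) {
    shuffle_idx(order, rng);
    for (int t = 0; t < l; ++t) {
      int k = order[t];
      if (nrm2[k] <= 1e-12) continue;
      double G = y[k] * col_dot_w(X, k, w) - 1.0;
      double a_old = alpha[k];
      double PG = G;
      if (a_old <= 0.0 && G > 0.0) PG = 0.0;
      if (a_old >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > 1e-12) {
        double a_new = std::min(C, std::max(0.0, a_old - G / nrm2[k]));
        double delta = a_new - a_old;
        if (delta != 0.0) { w_add_col(w, X, k, delta * y[k]); alpha[k] = a_new; }
      }
    }
    double w2 = 0.0;
    for (int r = 0; r < dim; ++r) w2 += w[r] * w[r];
    double hinge = 0.0, lin = 0.0;
    for (int k = 0; k < l; ++k) {
      double h = 1.0 - y[k] * col_dot_w(X, k, w);
      if (h > 0.0) hinge += h;
      lin += alpha[k];
    }
    primal = 0.5 * w2 + C * hinge;
    double dual = lin - 0.5 * w2;
    gap = primal - dual;
    trace.push_back(primal);
    if (gap <= tol * std::max(1.0, std::fabs(primal))) { converged = true; break; }
  }
  if (pass > max_iter) pass = max_iter;
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["objective"] = primal,
                      _["gap"] = gap,
                      _["iterations"] = pass,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged);
}

// Crammer-Singer multi-class SVM, sequential dual method.
// Primal: 0.5 sum_k ||w_k||^2 + C sum_i [max_k (w_k'x_i + e_ik) - w_{y_i}'x_i]
// with e_ik = 1 - delta(k, y_i). Dual variables tau_ik satisfy
// tau_ik <= C*delta(k,y_i), sum_k tau_ik = 0, and w_k = sum_i tau_ik x_i.
// [[Rcpp::export(name = ".mcsvm_dual_cd")]]
List mcsvm_dual_cd(S4 Xs4, IntegerVector y, int K, double C, double tol,
                   int max_iter, int seed) {
  IntegerVector pslot, islot; NumericVector xslot;
  SparseCols X = wrap_dgc(Xs4, pslot, islot, xslot);
  const int l = X.ncol, dim = X.nrow;
  if (y.size() != l) stop("labels length must equal ncol(X)");
  for (int k = 0; k < l; ++k)
    if (y[k] < 0 || y[k] >= K) stop("class labels must lie in [0, K)");

  std::vector<double> W((size_t)K * dim, 0.0);
  std::vector<double> tau((size_t)l * K, 0.0);
  std::vector<double> nrm2(l);
  for (int k = 0; k < l; ++k) {
    nrm2[k] = col_norm2(X, k);
    if (nrm2[k] <= 1e-12) {
      // zero feature vector: its CS hinge is constant (= C); the matching
      // dual optimum caps tau on the true class without touching W
      for (int c = 0; c < K; ++c)
        tau[(size_t)k * K + c] = (c == y[k]) ? C : -C / (K - 1);
    }
  }

  std::vector<int> order(l);
  for (int k = 0; k < l; ++k) order[k] = k;
  uint32_t rng = (uint32_t)seed * 2654435761u + 521288629u;

  std::vector<double> g(K), b(K), capv(K), bp(K), tnew(K);
  std::vector<int> ord(K);
  std::vector<double> trace;
  double primal = 0.0, gap = R_PosInf;
  bool converged = false;
  int pass = 0;
  for (pass = 1; pass <= max_iter; ++pass) {
    shuffle_idx(order, rng);
    for (int t = 0; t < l; ++t) {
      int i = order[t];
      double A = nrm2[i];
      if (A <= 1e-12) continue;
      for (int k = 0; k < K; ++k) {
        double wx = 0.0;
        for (int u = X.p[i]; u < X.p[i + 1]; ++u)
          wx += W[(size_t)k * dim + X.i[u]] * X.x[u];
        g[k] = wx + (k == y[i] ? 0.0 : 1.0);
        capv[k] = (k == y[i]) ? C : 0.0;
        b[k] = g[k] - A * tau[(size_t)i * K + k];
        bp[k] = b[k] + A * capv[k];  // breakpoint where coordinate saturates
        ord[k] = k;
      }
      // find beta with sum_k min(cap_k, (beta - b_k)/A) = 0
      std::sort(ord.begin(), ord.end(),
                [&](int a2, int b2) { return bp[a2] > bp[b2]; });
      double cap_total = C, sum_b = 0.0, beta = 0.0;
      for (int r = 0; r < K; ++r) {
        int k = ord[r];
        cap_total -= capv[k];
        sum_b += b[k];
        beta = (sum_b - A * cap_total) / (r + 1);
        if (r == K - 1 || beta > bp[ord[r + 1]]) break;
      }
      for (int k = 0; k < K; ++k)
        tnew[k] = std::min(capv[k], (beta - b[k]) / A);
      for (int k = 0; k < K; ++k) {
        double delta = tnew[k] - tau[(size_t)i * K + k];
        if (std::fabs(delta) > 0.0) {
          for (int u = X.p[i]; u < X.p[i + 1]; ++u)
            W[(size_t)k * dim + X.i[u]] += delta * X.x[u];
          tau[(size_t)i * K + k] = tnew[k];
        }
      }
    }
    // duality gap
    double w2 = 0.0;
    for (size_t r = 0; r < W.size(); ++r) w2 += W[r] * W[r];
    double xi_sum = 0.0, etau = 0.0;
    for (int i = 0; i < l; ++i) {
      double best = -HUGE_VAL, fy = 0.0;
      for (int k = 0; k < K; ++k) {
        double wx = 0.0;
        for (int u = X.p[i]; u < X.p[i + 1]; ++u)
          wx += W[(size_t)k * dim + X.i[u]] * X.x[u];
        double v = wx + (k == y[i] ? 0.0 : 1.0);
        if (v > best) best = v;
        if (k == y[i]) fy = wx;
      }
      xi_sum += best - fy;
      etau -= tau[(size_t)i * K + y[i]];  // sum_k e_ik tau_ik = -tau_{i,y_i}
    }
    primal = 0.5 * w2 + C * xi_sum;
    double dual = -0.5 * w2 - etau;
    gap = primal - dual;
    trace.push_back(primal);
    if (gap <= tol * std::max(1.0, std::fabs(primal))) { converged = true; break; }
  }
  if (pass > max_iter) pass = max_iter;
  NumericMatrix Wout(dim, K);
  for (int k = 0; k < K; ++k)
    for (int r = 0; r < dim; ++r) Wout(r, k) = W[(size_t)k * dim + r];
  return List::create(_["W"] = Wout,
                      _["objective"] = primal,
                      _["gap"] = gap,
                      _["iterations"] = pass,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged);
}

// FNV-1a over the little-endian bytes of a 32-bit integer sequence.
// Returned as double (a uint32 is exactly representable) so R can fold it
// modulo the fingerprint hash space without losing bits.
// [[Rcpp::export(name = ".fnv1a_hash")]]
double fnv1a_hash(IntegerVector v) {
  uint32_t h = 2166136261u;
  for (R_xlen_t j = 0; j < v.size(); ++j) {
    uint32_t x = (uint32_t)v[j];
    for (int b = 0; b < 4; ++b) {
      h ^= (x >> (8 * b)) & 0xffu;
      h *= 16777619u;
    }
  }
  return (double)h;
}
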