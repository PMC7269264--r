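// Graphical lasso by blockwise coordinate descent (Friedman-style), with an
// EBIC-scored lambda path. The diagonal is not penalized, so at the optimum
// the working covariance W satisfies W_ii = S_ii and, off-diagonal,
// W_ij - S_ij = lambda * sign(K_ij) on the support, |W_ij - S_ij| <= lambda
// off it (the KKT system checked below).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double soft(double x, double t) {
  double a = std::abs(x) - t;
  return a > 0.0 ? (x > 0.0 ? a : -a) : 0.0;
}

// minimize 0.5 b'Vb - u'b + lambda ||b||_1 by cyclic coordinate descent
static void lasso_cd(const mat& V, const vec& u, vec& b, double lambda,
                     double tol, int maxit) {
  const uword m = b.n_elem;
  vec Vb = V * b;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (uword k = 0; k < m; ++k) {
      double grad = u[k] - Vb[k] + V(k, k) * b[k];
      double bnew = soft(grad, lambda) / V(k, k);
      double d = bnew - b[k];
      if (d != 0.0) {
        b[k] = bnew;
        Vb += d * V.col(k);
        double ad = std::abs(d);
        if (ad > maxdiff) maxdiff = ad;
      }
    }
    if (maxdiff < tol) break;
  }
}

// One glasso fit at fixed lambda, warm-started from W and B.
// B is p x p with column j holding beta for column j (entry j unused, 0).
static void glasso_fit_ws(const mat& S, double lambda, mat& W, mat& B,
                          double tol, int max_sweeps) {
  const uword p = S.n_rows;
  if (p == 1) { W = S; return; }
  uvec all = regspace<uvec>(0, p - 1);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double maxchg = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat V = W.submat(idx, idx);
      vec u = S.col(j);
      u = u.elem(idx);
      vec b = B.col(j);
      b = b.elem(idx);
      lasso_cd(V, u, b, lambda, tol * 0.1, 1000);
      vec w12 = V * b;
      vec old = W.col(j);
      old = old.elem(idx);
      double chg = abs(w12 - old).max();
      if (chg > maxchg) maxchg = chg;
      for (uword t = 0; t < idx.n_elem; ++t) {
        W(idx[t], j) = w12[t];
        W(j, idx[t]) = w12[t];
        B(idx[t], j) = b[t];
      }
    }
    if (maxchg < tol) break;
  }
}

// Recover the precision matrix from (W, B).
static mat recover_K(const mat& W, const mat& B) {
  const uword p = W.n_rows;
  mat K(p, p, fill::zeros);
  if (p == 1) { K(0, 0) = 1.0 / W(0, 0); return K; }
  uvec all = regspace<uvec>(0, p - 1);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec b = B.col(j);
    b = b.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double k22 = 1.0 / (W(j, j) - dot(w12, b));
    K(j, j) = k22;
    for (uword t = 0; t < idx.n_elem; ++t) K(idx[t], j) = -b[t] * k22;
  }
  return 0.5 * (K + K.t());
}

static double kkt_residual(const mat& S, const mat& W, const mat& K,
                           double lambda, double zero_tol) {
  const uword p = S.n_rows;
  double worst = 0.0;
  for (uword j = 0; j < p; ++j) {
    for (uword i = 0; i < p; ++i) {
      if (i == j) continue;
      double d = W(i, j) - S(i, j);
      double r;
      if (std::abs(K(i, j)) > zero_tol) {
        r = std::abs(d - lambda * (K(i, j) > 0 ? 1.0 : -1.0));
      } else {
        r = std::max(0.0, std::abs(d) - lambda);
      }
      if (r > worst) worst = r;
    }
  }
  return worst;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda, double tol = 1e-7,
                      int max_sweeps = 500) {
  const uword p = S.n_rows;
  mat W = S;
  mat B(p, p, fill::zeros);
  glasso_fit_ws(S, lambda, W, B, tol, max_sweeps);
  mat K = recover_K(W, B);
  double kkt = kkt_residual(S, W, K, lambda, 1e-12);
  return Rcpp::List::create(Rcpp::Named("K") = K, Rcpp::Named("W_cov") = W,
                            Rcpp::Named("kkt") = kkt);
}

// Fit a descending lambda path with warm starts; EBIC-score each fit.
// Returns per-lambda EBIC, log-likelihood term, edge count, and the
// precision matrix at the EBIC minimum.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double n, double gamma, double tol = 1e-7,
                           int max_sweeps = 500) {
  const uword p = S.n_rows;
  const uword L = lambdas.n_elem;
  mat W = S;
  mat B(p, p, fill::zeros);
  vec ebic(L), loglik(L), kkt(L);
  ivec edges(L);
  mat bestK;
  double best = datum::inf;
  int best_idx = -1;
  const double logp = std::log(static_cast<double>(p));
  for (uword l = 0; l < L; ++l) {
    glasso_fit_ws(S, lambdas[l], W, B, tol, max_sweeps);
    mat K = recover_K(W, B);
    kkt[l] = kkt_residual(S, W, K, lambdas[l], 1e-12);
    double ld, sign;
    log_det(ld, sign, K);
    double ll = ld - trace(S * K);
    int E = 0;
    for (uword j = 1; j < p; ++j)
      for (uword i = 0; i < j; ++i)
        if (std::abs(K(i, j)) > 1e-10) ++E;
    double score = -n * ll + E * std::log(n) + 4.0 * E * gamma * logp;
    loglik[l] = ll;
    edges[l] = E;
    ebic[l] = score;
    if (score < best) {
      best = score;
      best_idx = static_cast<int>(l);
      bestK = K;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("ebic") = ebic, Rcpp::Named("loglik") = loglik,
      Rcpp::Named("edges") = edges, Rcpp::Named("kkt") = kkt,
      Rcpp::Named("best_index") = best_idx + 1, Rcpp::Named("K") = bestK);
}

// Pairwise Kendall tau-b matrix, O(n^2) per pair with tie corrections.
// [[Rcpp::export(name = ".kendall_matrix_cpp")]]
arma::mat kendall_matrix_cpp(const arma::mat& X) {
  const uword n = X.n_rows, p = X.n_cols;
  mat T(p, p, fill::eye);
  for (uword a = 0; a < p; ++a) {
    for (uword b = a + 1; b < p; ++b) {
      const double* x = X.colptr(a);
      const double* y = X.colptr(b);
      long long C = 0, D = 0, tx = 0, ty = 0;
      for (uword i = 0; i + 1 < n; ++i) {
        for (uword j = i + 1; j < n; ++j) {
          double dx = x[j] - x[i], dy = y[j] - y[i];
          if (dx == 0.0 && dy == 0.0) continue;
          if (dx == 0.0) ++tx;
          else if (dy == 0.0) ++ty;
          else if ((dx > 0.0) == (dy > 0.0)) ++C;
          else ++D;
        }
      }
      double n0 = 0.5 * static_cast<double>(n) * (n - 1);
      double nx = n0 - C - D - ty;  // pairs tied in x (incl. tied in both)
      double ny = n0 - C - D - tx;  // pairs tied in y
      double denom = std::sqrt((n0 - nx) * (n0 - ny));
      T(a, b) = T(b, a) = denom > 0 ? (C - D) / denom : NA_REAL;
    }
  }
  return T;
}
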