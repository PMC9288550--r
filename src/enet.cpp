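// Elastic-net coordinate descent and its repeated-CV driver.
//
// Objective (intercept unpenalized):
//   (1/2n) * sum_i (y_i - mu - x_i' beta)^2
//     + lambda * ( (1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1 )
//
// Coordinate updates use the covariance formulation (precomputed X'X/n and
// X'y/n), so one full sweep costs O(p^2) regardless of n.  The CV driver
// standardizes predictors with training-split means/SDs (denominator n-1)
// applied to the held-out fold, so no information leaks from test to
// train.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Coordinate descent on the covariance statistics of centred data:
// G = X'X/n (p x p), c = X'y/n.  grad = G * beta is maintained
// incrementally.  beta is warm-started in place.  Returns iterations
// used, or -1 if the cap was hit.
static int cd_solve_cov(const std::vector<double>& G,
                        const std::vector<double>& c, int p,
                        double alpha, double lambda,
                        std::vector<double>& beta,
                        std::vector<double>& grad,
                        double tol, int maxit) {
  const double l1 = lambda * alpha;
  const double l2 = lambda * (1.0 - alpha);
  // grad for current beta
  for (int j = 0; j < p; ++j) grad[j] = 0.0;
  for (int k = 0; k < p; ++k) {
    if (beta[k] != 0.0) {
      const double* gk = &G[(size_t)k * p];
      for (int j = 0; j < p; ++j) grad[j] += gk[j] * beta[k];
    }
  }
  for (int it = 1; it <= maxit; ++it) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      const double gjj = G[(size_t)j * p + j];
      const double denom = gjj + l2;
      if (denom <= 0.0) { beta[j] = 0.0; continue; }
      double rho = c[j] - grad[j] + gjj * beta[j];
      double bnew = soft_threshold(rho, l1) / denom;
      double d = bnew - beta[j];
      if (d != 0.0) {
        const double* gj = &G[(size_t)j * p];
        for (int k = 0; k < p; ++k) grad[k] += gj[k] * d;
        beta[j] = bnew;
        double ad = std::fabs(d);
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (max_delta < tol) return it;
  }
  return -1;
}

// [[Rcpp::export]]
List enet_fit_cpp(NumericMatrix Xr, NumericVector yr, double alpha,
                  double lambda, double tol = 1e-9, int maxit = 100000) {
  const int n = Xr.nrow(), p = Xr.ncol();
  std::vector<double> X(Xr.begin(), Xr.end());
  std::vector<double> xm(p);
  std::vector<double> y(n);
  double ym = 0.0;
  for (int i = 0; i < n; ++i) ym += yr[i];
  ym /= n;
  for (int i = 0; i < n; ++i) y[i] = yr[i] - ym;
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    double* xj = &X[(size_t)j * n];
    for (int i = 0; i < n; ++i) m += xj[i];
    m /= n;
    xm[j] = m;
    for (int i = 0; i < n; ++i) xj[i] -= m;
  }
  std::vector<double> G((size_t)p * p), c(p);
  for (int j = 0; j < p; ++j) {
    const double* xj = &X[(size_t)j * n];
    double cj = 0.0;
    for (int i = 0; i < n; ++i) cj += xj[i] * y[i];
    c[j] = cj / n;
    for (int k = j; k < p; ++k) {
      const double* xk = &X[(size_t)k * n];
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xj[i] * xk[i];
      G[(size_t)j * p + k] = G[(size_t)k * p + j] = s / n;
    }
  }
  std::vector<double> beta(p, 0.0), grad(p);
  int it = cd_solve_cov(G, c, p, alpha, lambda, beta, grad, tol, maxit);
  double intercept = ym;
  for (int j = 0; j < p; ++j) intercept -= beta[j] * xm[j];
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["intercept"] = intercept,
                      _["iterations"] = it,
                      _["converged"] = it > 0);
}

// Per-split working data: standardized train covariance statistics and
// the standardized test block.
struct SplitData {
  int ntr, nte;
  double ym;                       // train outcome mean
  std::vector<double> G, c;        // X'X/n, X'y/n on standardized train
  std::vector<double> Xte;         // standardized test block (col-major)
  std::vector<int> te;             // test row indices
};

// Standardize with training means/SDs (sample SD, denominator n-1);
// columns with zero training SD become all-zero.  With !scale_cols the
// columns are centred only (caller pre-scaled the matrix).
static void build_split(const NumericMatrix& X, const NumericVector& y,
                        const std::vector<int>& tr,
                        const std::vector<int>& te,
                        bool scale_cols, SplitData& sd_out) {
  const int p = X.ncol();
  const int ntr = (int)tr.size(), nte = (int)te.size();
  sd_out.ntr = ntr; sd_out.nte = nte;
  sd_out.te = te;
  std::vector<double> Xtr((size_t)p * ntr);
  sd_out.Xte.assign((size_t)p * nte, 0.0);
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (int i = 0; i < ntr; ++i) m += X(tr[i], j);
    m /= ntr;
    double ss = 0.0;
    for (int i = 0; i < ntr; ++i) {
      double d = X(tr[i], j) - m;
      ss += d * d;
    }
    double sd = ntr > 1 ? std::sqrt(ss / (ntr - 1)) : 0.0;
    double inv = sd > 1e-12 ? 1.0 / sd : 0.0;
    if (!scale_cols) inv = 1.0;
    for (int i = 0; i < ntr; ++i)
      Xtr[(size_t)j * ntr + i] = (X(tr[i], j) - m) * inv;
    for (int i = 0; i < nte; ++i)
      sd_out.Xte[(size_t)j * nte + i] = (X(te[i], j) - m) * inv;
  }
  double ym = 0.0;
  for (int i = 0; i < ntr; ++i) ym += y[tr[i]];
  ym /= ntr;
  sd_out.ym = ym;
  sd_out.G.assign((size_t)p * p, 0.0);
  sd_out.c.assign(p, 0.0);
  for (int j = 0; j < p; ++j) {
    const double* xj = &Xtr[(size_t)j * ntr];
    double cj = 0.0;
    for (int i = 0; i < ntr; ++i) cj += xj[i] * (y[tr[i]] - ym);
    sd_out.c[j] = cj / ntr;
    for (int k = j; k < p; ++k) {
      const double* xk = &Xtr[(size_t)k * ntr];
      double s = 0.0;
      for (int i = 0; i < ntr; ++i) s += xj[i] * xk[i];
      sd_out.G[(size_t)j * p + k] = sd_out.G[(size_t)k * p + j] = s / ntr;
    }
  }
}

static double split_test_rmse(const SplitData& sd, const NumericVector& y,
                              const std::vector<double>& beta, int p) {
  double sse = 0.0;
  for (int i = 0; i < sd.nte; ++i) {
    double pred = sd.ym;
    for (int j = 0; j < p; ++j)
      pred += sd.Xte[(size_t)j * sd.nte + i] * beta[j];
    double e = y[sd.te[i]] - pred;
    sse += e * e;
  }
  return std::sqrt(sse / sd.nte);
}

// Mean over splits of the test RMSE at every (alpha, lambda) grid point.
// fold_id: n x n_repeats matrix of fold labels 1..K.  lambda_grid is
// traversed from largest to smallest with warm starts within each alpha.
// [[Rcpp::export]]
NumericMatrix enet_cv_grid_cpp(NumericMatrix X, NumericVector y,
                               IntegerMatrix fold_id,
                               NumericVector alpha_grid,
                               NumericVector lambda_grid,
                               double tol = 1e-4, int maxit = 5000,
                               bool scale_cols = true) {
  const int n = X.nrow(), p = X.ncol();
  const int R = fold_id.ncol();
  const int A = alpha_grid.size(), L = lambda_grid.size();
  std::vector<int> lord(L);
  for (int l = 0; l < L; ++l) lord[l] = l;
  std::sort(lord.begin(), lord.end(), [&](int a, int b) {
    return lambda_grid[a] > lambda_grid[b];
  });
  NumericMatrix acc(A, L);
  int n_splits = 0;
  std::vector<double> beta(p), grad(p);
  SplitData sd;
  for (int r = 0; r < R; ++r) {
    int K = 0;
    for (int i = 0; i < n; ++i) K = std::max(K, fold_id(i, r));
    for (int k = 1; k <= K; ++k) {
      std::vector<int> tr, te;
      for (int i = 0; i < n; ++i)
        (fold_id(i, r) == k ? te : tr).push_back(i);
      if (te.empty() || tr.size() < 2) continue;
      ++n_splits;
      build_split(X, y, tr, te, scale_cols, sd);
      for (int a = 0; a < A; ++a) {
        std::fill(beta.begin(), beta.end(), 0.0);
        for (int li = 0; li < L; ++li) {
          const int l = lord[li];
          cd_solve_cov(sd.G, sd.c, p, alpha_grid[a], lambda_grid[l],
                       beta, grad, tol, maxit);
          acc(a, l) += split_test_rmse(sd, y, beta, p);
        }
      }
    }
  }
  for (int a = 0; a < A; ++a)
    for (int l = 0; l < L; ++l) acc(a, l) /= n_splits;
  return acc;
}

// Refit at fixed (alpha, lambda) on every training split; collect the
// per-split test RMSE and the per-split coefficients on the z-scale.
// [[Rcpp::export]]
List enet_refit_splits_cpp(NumericMatrix X, NumericVector y,
                           IntegerMatrix fold_id, double alpha,
                           double lambda, double tol = 1e-9,
                           int maxit = 100000, bool scale_cols = true) {
  const int n = X.nrow(), p = X.ncol();
  const int R = fold_id.ncol();
  std::vector<double> beta(p), grad(p);
  std::vector<double> rmses;
  std::vector<std::vector<double>> betas;
  SplitData sd;
  for (int r = 0; r < R; ++r) {
    int K = 0;
    for (int i = 0; i < n; ++i) K = std::max(K, fold_id(i, r));
    for (int k = 1; k <= K; ++k) {
      std::vector<int> tr, te;
      for (int i = 0; i < n; ++i)
        (fold_id(i, r) == k ? te : tr).push_back(i);
      if (te.empty() || tr.size() < 2) continue;
      build_split(X, y, tr, te, scale_cols, sd);
      std::fill(beta.begin(), beta.end(), 0.0);
      cd_solve_cov(sd.G, sd.c, p, alpha, lambda, beta, grad, tol, maxit);
      rmses.push_back(split_test_rmse(sd, y, beta, p));
      betas.push_back(beta);
    }
  }
  const int S = (int)rmses.size();
  NumericMatrix B(S, p);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < p; ++j) B(s, j) = betas[s][j];
  return List::create(_["rmse"] = NumericVector(rmses.begin(), rmses.end()),
                      _["beta"] = B);
}
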