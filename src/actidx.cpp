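// Hot numerical kernels for the nested leave-one-out classifier:
// unregularized logistic IRLS (with a finite coefficient cap under
// separation), exact leave-one-out accuracy, sequential forward selection
// and greedy MID-scheme mRMR ranking. The nested CV needs on the order of
// 10^5-10^6 small logistic fits per task, which rules out glm() in the loop;
// stats::glm serves as the independent cross-check in the test suite.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// In-place Cholesky solve of A x = b for symmetric positive-definite A
// (row-major d x d). Returns false if the factorization fails.
static bool chol_solve(std::vector<double>& A, std::vector<double>& b, int d) {
  for (int j = 0; j < d; ++j) {
    double s = A[j * d + j];
    for (int k = 0; k < j; ++k) s -= A[j * d + k] * A[j * d + k];
    if (s <= 0.0) return false;
    double l = std::sqrt(s);
    A[j * d + j] = l;
    for (int i = j + 1; i < d; ++i) {
      double t = A[i * d + j];
      for (int k = 0; k < j; ++k) t -= A[i * d + k] * A[j * d + k];
      A[i * d + j] = t / l;
    }
  }
  for (int i = 0; i < d; ++i) {
    double t = b[i];
    for (int k = 0; k < i; ++k) t -= A[i * d + k] * b[k];
    b[i] = t / A[i * d + i];
  }
  for (int i = d - 1; i >= 0; --i) {
    double t = b[i];
    for (int k = i + 1; k < d; ++k) t -= A[k * d + i] * b[k];
    b[i] = t / A[i * d + i];
  }
  return true;
}

struct FitResult {
  bool converged;
  bool capped;
};

// IRLS over rows of X (n x p, column-major from R) restricted to feature
// columns `cols` (0-based, size q), skipping row `skip` (-1 for none).
// beta has length q + 1, intercept first; used as warm start and overwritten.
static FitResult irls(const double* X, int n, int p,
                      const std::vector<int>& cols, const double* y,
                      int skip, std::vector<double>& beta,
                      double cap, int maxit, double tol) {
  const int q = (int)cols.size();
  const int d = q + 1;
  std::vector<double> A(d * d), rhs(d), xr(d);
  FitResult res{false, false};
  (void)p;
  for (int it = 0; it < maxit; ++it) {
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(rhs.begin(), rhs.end(), 0.0);
    for (int r = 0; r < n; ++r) {
      if (r == skip) continue;
      xr[0] = 1.0;
      double eta = beta[0];
      for (int j = 0; j < q; ++j) {
        double v = X[(size_t)cols[j] * n + r];
        xr[j + 1] = v;
        eta += beta[j + 1] * v;
      }
      double mu = 1.0 / (1.0 + std::exp(-eta));
      double w = mu * (1.0 - mu);
      if (w < 1e-10) w = 1e-10;
      double resid = y[r] - mu;
      for (int i = 0; i < d; ++i) {
        rhs[i] += xr[i] * resid;
        for (int j = 0; j <= i; ++j) A[i * d + j] += w * xr[i] * xr[j];
      }
    }
    for (int i = 0; i < d; ++i) {
      A[i * d + i] += 1e-10;  // numerical jitter only
      for (int j = i + 1; j < d; ++j) A[i * d + j] = A[j * d + i];
    }
    std::vector<double> step(rhs);
    std::vector<double> Ac(A);
    if (!chol_solve(Ac, step, d)) {
      for (int i = 0; i < d; ++i) A[i * d + i] += 1e-6;
      Ac = A; step = rhs;
      if (!chol_solve(Ac, step, d)) return res;
    }
    double maxstep = 0.0;
    for (int i = 0; i < d; ++i) {
      beta[i] += step[i];
      if (beta[i] > cap) { beta[i] = cap; res.capped = true; }
      if (beta[i] < -cap) { beta[i] = -cap; res.capped = true; }
      maxstep = std::max(maxstep, std::fabs(step[i]));
    }
    if (maxstep < tol) { res.converged = true; break; }
  }
  return res;
}

static double predict_prob(const double* X, int n, const std::vector<int>& cols,
                           int row, const std::vector<double>& beta) {
  double eta = beta[0];
  for (size_t j = 0; j < cols.size(); ++j)
    eta += beta[j + 1] * X[(size_t)cols[j] * n + row];
  return 1.0 / (1.0 + std::exp(-eta));
}

// [[Rcpp::export]]
List cpp_fit_logistic(NumericMatrix X, NumericVector y, double cap = 15.0,
                      int maxit = 50, double tol = 1e-8) {
  int n = X.nrow(), p = X.ncol();
  std::vector<int> cols(p);
  for (int j = 0; j < p; ++j) cols[j] = j;
  std::vector<double> beta(p + 1, 0.0);
  FitResult fr = irls(REAL(X), n, p, cols, REAL(y), -1, beta, cap, maxit, tol);
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["converged"] = fr.converged, _["capped"] = fr.capped);
}

static double loo_accuracy_cols(const double* X, int n, int p,
                                const std::vector<int>& cols, const double* y,
                                double cap) {
  std::vector<double> beta_full(cols.size() + 1, 0.0);
  irls(X, n, p, cols, y, -1, beta_full, cap, 50, 1e-8);
  int correct = 0;
  std::vector<double> beta(beta_full.size());
  for (int i = 0; i < n; ++i) {
    beta = beta_full;  // warm start from the all-rows fit
    irls(X, n, p, cols, y, i, beta, cap, 25, 1e-7);
    double pr = predict_prob(X, n, cols, i, beta);
    bool pred = pr > 0.5;
    bool truth = y[i] > 0.5;
    if (pred == truth) ++correct;
  }
  return (double)correct / n;
}

// [[Rcpp::export]]
double cpp_loo_accuracy(NumericMatrix X, NumericVector y, IntegerVector cols,
                        double cap = 15.0) {
  std::vector<int> c0(cols.size());
  for (int j = 0; j < cols.size(); ++j) c0[j] = cols[j] - 1;
  return loo_accuracy_cols(REAL(X), X.nrow(), X.ncol(), c0, REAL(y), cap);
}

// [[Rcpp::export]]
List cpp_loo_predict(NumericMatrix X, NumericVector y, IntegerVector cols,
                     double cap = 15.0) {
  int n = X.nrow();
  std::vector<int> c0(cols.size());
  for (int j = 0; j < cols.size(); ++j) c0[j] = cols[j] - 1;
  std::vector<double> beta_full(c0.size() + 1, 0.0);
  irls(REAL(X), n, X.ncol(), c0, REAL(y), -1, beta_full, cap, 50, 1e-8);
  NumericVector probs(n);
  std::vector<double> beta(beta_full.size());
  for (int i = 0; i < n; ++i) {
    beta = beta_full;
    irls(REAL(X), n, X.ncol(), c0, REAL(y), i, beta, cap, 25, 1e-7);
    probs[i] = predict_prob(REAL(X), n, c0, i, beta);
  }
  return List::create(_["probs"] = probs,
                      _["beta_all"] = NumericVector(beta_full.begin(), beta_full.end()));
}

// Forward selection driven by inner leave-one-out accuracy. candidates are
// 1-based column indices in preference (mRMR) order; ties in accuracy go to
// the earlier candidate. base_acc is the empty-model reference accuracy.
// [[Rcpp::export]]
IntegerVector cpp_sfs(NumericMatrix X, NumericVector y, IntegerVector candidates,
                      int max_features, double cap, double base_acc) {
  int n = X.nrow(), p = X.ncol();
  std::vector<int> selected;
  std::vector<bool> used(candidates.size(), false);
  double cur = base_acc;
  while ((int)selected.size() < max_features) {
    int best_k = -1;
    double best_acc = cur;
    std::vector<int> trial(selected.size() + 1);
    std::copy(selected.begin(), selected.end(), trial.begin());
    for (int k = 0; k < candidates.size(); ++k) {
      if (used[k]) continue;
      trial.back() = candidates[k] - 1;
      double acc = loo_accuracy_cols(REAL(X), n, p, trial, REAL(y), cap);
      if (acc > best_acc + 1e-12) { best_acc = acc; best_k = k; }
    }
    if (best_k < 0) break;
    used[best_k] = true;
    selected.push_back(candidates[best_k] - 1);
    cur = best_acc;
  }
  IntegerVector out(selected.size());
  for (size_t j = 0; j < selected.size(); ++j) out[j] = selected[j] + 1;
  return out;
}

// Mutual information (nats) between two discrete codes in {0..a-1},{0..b-1}.
static double mutual_info(const int* x, const int* y, int n, int a, int b) {
  std::vector<double> joint(a * b, 0.0), px(a, 0.0), py(b, 0.0);
  for (int i = 0; i < n; ++i) {
    joint[x[i] * b + y[i]] += 1.0;
    px[x[i]] += 1.0;
    py[y[i]] += 1.0;
  }
  double mi = 0.0;
  for (int i = 0; i < a; ++i)
    for (int j = 0; j < b; ++j) {
      double pij = joint[i * b + j];
      if (pij > 0.0)
        mi += (pij / n) * std::log(pij * n / (px[i] * py[j]));
    }
  return mi < 0.0 ? 0.0 : mi;
}

// Greedy MID-scheme mRMR over pre-discretized features D (n x p, codes
// 0..nbins-1) against binary labels y (0/1). Ties break to the lower column
// index (registry order). Returns 1-based indices of the top k features.
// [[Rcpp::export]]
IntegerVector cpp_mrmr(IntegerMatrix D, IntegerVector y, int k, int nbins = 3) {
  int n = D.nrow(), p = D.ncol();
  if (k <= 0) stop("k must be positive");
  if (k > p) k = p;
  std::vector<double> rel(p), redsum(p, 0.0);
  const int* dptr = INTEGER(D);
  for (int j = 0; j < p; ++j)
    rel[j] = mutual_info(dptr + (size_t)j * n, INTEGER(y), n, nbins, 2);
  std::vector<bool> used(p, false);
  IntegerVector out(k);
  for (int step = 0; step < k; ++step) {
    int best = -1;
    double best_score = -1e300;
    for (int j = 0; j < p; ++j) {
      if (used[j]) continue;
      double score = (step == 0) ? rel[j] : rel[j] - redsum[j] / step;
      if (score > best_score + 1e-15) { best_score = score; best = j; }
    }
    used[best] = true;
    out[step] = best + 1;
    if (step + 1 < k) {
      const int* sb = dptr + (size_t)best * n;
      for (int j = 0; j < p; ++j) {
        if (used[j]) continue;
        redsum[j] += mutual_info(dptr + (size_t)j * n, sb, n, nbins, nbins);
      }
    }
  }
  return out;
}

// Equal-frequency discretization of each column into nbins codes 0..nbins-1
// using type-7 quantile cut points computed on the same matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_discretize(NumericMatrix X, int nbins = 3) {
  int n = X.nrow(), p = X.ncol();
  IntegerMatrix D(n, p);
  std::vector<double> col(n), cuts(nbins - 1);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) col[i] = X(i, j);
    std::vector<double> srt(col);
    std::sort(srt.begin(), srt.end());
    for (int b = 1; b < nbins; ++b) {
      double h = (n - 1) * (double)b / nbins;
      int lo = (int)std::floor(h);
      double q = srt[lo];
      if (lo + 1 < n) q += (h - lo) * (srt[lo + 1] - srt[lo]);
      cuts[b - 1] = q;
    }
    for (int i = 0; i < n; ++i) {
      int code = 0;
      for (int b = 0; b < nbins - 1; ++b)
        if (col[i] > cuts[b]) code = b + 1;
      D(i, j) = code;
    }
  }
  return D;
}
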