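#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Elastic-net coordinate descent with covariance updates.
//
// Minimizes, over beta (intercept handled by the caller via centering):
//   (1/(2n)) * ||y - X beta||^2 + lambda * sum_j [ (1-alpha)/2 beta_j^2
//                                                  + alpha |beta_j| ]
// given the sufficient statistics XtX = X'X, Xty = X'y and yty = y'y.
// Each coordinate update costs O(p), independent of n.  Lambdas must be
// in decreasing order; solutions are warm-started along the path.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static inline double objective(const NumericMatrix& XtX,
                               const NumericVector& Xty, double yty,
                               const NumericVector& beta, int n,
                               double lambda, double alpha) {
  const int p = beta.size();
  double quad = 0.0, lin = 0.0, pen = 0.0;
  for (int j = 0; j < p; ++j) {
    if (beta[j] == 0.0) continue;
    lin += beta[j] * Xty[j];
    for (int k = 0; k < p; ++k) {
      if (beta[k] != 0.0) quad += beta[j] * XtX(j, k) * beta[k];
    }
    pen += 0.5 * (1.0 - alpha) * beta[j] * beta[j] + alpha * std::fabs(beta[j]);
  }
  return (yty - 2.0 * lin + quad) / (2.0 * n) + lambda * pen;
}

// [[Rcpp::export(name = ".cd_path")]]
List cd_path(NumericMatrix XtX, NumericVector Xty, double yty, int n,
             NumericVector lambdas, double alpha, double tol, int max_iter,
             Nullable<NumericVector> warm_start = R_NilValue,
             bool trace_objective = false) {
  const int p = Xty.size();
  const int nlam = lambdas.size();
  NumericMatrix betas(p, nlam);
  IntegerVector n_iter(nlam);
  LogicalVector converged(nlam);
  List traces(trace_objective ? nlam : 0);

  NumericVector beta(p);
  if (warm_start.isNotNull()) {
    NumericVector w(warm_start);
    if (w.size() != p) stop("warm_start length mismatch");
    for (int j = 0; j < p; ++j) beta[j] = w[j];
  }

  // residual inner products r_j = <x_j, y - X beta> maintained incrementally
  NumericVector r(p);
  for (int j = 0; j < p; ++j) {
    double s = Xty[j];
    for (int k = 0; k < p; ++k) s -= XtX(j, k) * beta[k];
    r[j] = s;
  }

  for (int l = 0; l < nlam; ++l) {
    const double lambda = lambdas[l];
    const double l1 = lambda * alpha;
    const double l2 = lambda * (1.0 - alpha);
    std::vector<double> obj_trace;
    int it = 0;
    bool conv = false;
    for (it = 0; it < max_iter; ++it) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double xjj = XtX(j, j);
        if (xjj <= 0.0) { continue; }  // constant column: stays at 0
        const double bj_old = beta[j];
        const double z = r[j] / n + (xjj / n) * bj_old;
        const double bj = soft(z, l1) / (xjj / n + l2);
        const double delta = bj - bj_old;
        if (delta != 0.0) {
          beta[j] = bj;
          for (int k = 0; k < p; ++k) r[k] -= XtX(k, j) * delta;
          double ad = std::fabs(delta);
          if (ad > max_delta) max_delta = ad;
        }
      }
      if (trace_objective) {
        obj_trace.push_back(objective(XtX, Xty, yty, beta, n, lambda, alpha));
      }
      if (max_delta < tol) { conv = true; ++it; break; }
    }
    n_iter[l] = it;
    converged[l] = conv;
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    if (trace_objective) traces[l] = wrap(obj_trace);
  }

  List out = List::create(_["beta"] = betas,
                          _["n_iter"] = n_iter,
                          _["converged"] = converged);
  if (trace_objective) out["objective_trace"] = traces;
  return out;
}
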