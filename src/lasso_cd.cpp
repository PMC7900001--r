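// Coordinate-descent lasso on sufficient statistics, with rank-one
// leave-one-out downdates. Working on (X'X, X'y, colsums) makes each
// LOOCV fold O(p^2) instead of O(n p), which is what keeps the fully
// nested penalty-selection cross-validation tractable.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Stats {
  mat S;        // X'X
  vec sx;       // column sums of X
  vec sy;       // X'y
  double ysum;
  double yss;   // y'y
  double n;
};

Stats full_stats(const mat& X, const vec& y) {
  Stats st;
  st.S = X.t() * X;
  st.sx = sum(X, 0).t();
  st.sy = X.t() * y;
  st.ysum = accu(y);
  st.yss = dot(y, y);
  st.n = (double)X.n_rows;
  return st;
}

void downdate(Stats& st, const rowvec& x, double y) {
  st.S -= x.t() * x;
  st.sx -= x.t();
  st.sy -= x.t() * y;
  st.ysum -= y;
  st.yss -= y * y;
  st.n -= 1.0;
}

// Standardized moments: C = cor-scaled Gram (unit diagonal), b = (1/n) Xs'yc.
// Columns with (near-)zero variance are inert: b = 0, off-diagonal C = 0.
struct Moments {
  mat C;
  vec b, m, sd;
  double ybar, vary;
  uvec active;
};

Moments standardize(const Stats& st) {
  Moments mo;
  const double n = st.n;
  const uword p = st.S.n_rows;
  mo.m = st.sx / n;
  vec v = st.S.diag() / n - mo.m % mo.m;
  v = clamp(v, 0.0, datum::inf);
  mo.sd = sqrt(v);
  mo.ybar = st.ysum / n;
  mo.vary = st.yss / n - mo.ybar * mo.ybar;
  if (mo.vary < 0) mo.vary = 0;
  mo.C = st.S / n - mo.m * mo.m.t();
  mo.b = st.sy / n - mo.m * mo.ybar;
  uvec act(p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    if (mo.sd(j) > 1e-10) { act(j) = 1; mo.b(j) /= mo.sd(j); }
    else mo.b(j) = 0.0;
  }
  for (uword j = 0; j < p; ++j) {
    for (uword k = 0; k < p; ++k) {
      if (act(j) && act(k)) mo.C(j, k) /= (mo.sd(j) * mo.sd(k));
      else mo.C(j, k) = 0.0;
    }
    mo.C(j, j) = 1.0;
  }
  mo.active = act;
  return mo;
}

inline double soft(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

// One coordinate-descent solve at a single lambda; beta is the warm start
// (standardized scale) and is overwritten. Returns sweeps used.
int cd_solve(const Moments& mo, double lambda, vec& beta,
             double tol, int maxit, std::vector<double>* obj_trace) {
  const uword p = beta.n_elem;
  for (uword j = 0; j < p; ++j) if (!mo.active(j)) beta(j) = 0.0;
  vec r = mo.b - mo.C * beta;  // gradient residual, kept up to date
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      if (!mo.active(j)) continue;
      double z = r(j) + beta(j);   // C(j,j) == 1
      double nb = soft(z, lambda);
      double d = nb - beta(j);
      if (d != 0.0) {
        r -= mo.C.col(j) * d;      // C symmetric: col == row
        beta(j) = nb;
        if (std::fabs(d) > delta) delta = std::fabs(d);
      }
    }
    if (obj_trace) {
      double quad = mo.vary - 2.0 * dot(beta, mo.b) +
        as_scalar(beta.t() * mo.C * beta);
      obj_trace->push_back(0.5 * quad + lambda * accu(abs(beta)));
    }
    if (delta < tol) return it + 1;
  }
  return maxit;
}

double lambda_max(const Moments& mo) {
  return mo.b.n_elem ? abs(mo.b).max() : 0.0;
}

vec make_grid(double lmax, int nlambda, double min_ratio) {
  if (lmax <= 1e-300) lmax = 1e-300;
  vec g(nlambda);
  double llo = std::log(lmax * min_ratio), lhi = std::log(lmax);
  for (int i = 0; i < nlambda; ++i)
    g(i) = std::exp(lhi + (llo - lhi) * i / std::max(1, nlambda - 1));
  return g;  // decreasing
}

double predict_one(const Moments& mo, const vec& beta, const rowvec& x) {
  double eta = mo.ybar;
  for (uword j = 0; j < beta.n_elem; ++j)
    if (mo.active(j) && beta(j) != 0.0)
      eta += beta(j) * (x(j) - mo.m(j)) / mo.sd(j);
  return eta;
}

// Leave-one-out SSE per grid penalty over the rows in `rows`, given the
// base statistics of those rows. The penalty loop is outermost so every
// fold warm-starts from its own solution at the previous (larger)
// penalty, and fold moments are standardized once.
vec loocv_grid_sse(const Stats& base, const mat& X, const vec& y,
                   const uvec& rows, const vec& grid_desc,
                   double tol, int maxit) {
  const uword p = X.n_cols, nf = rows.n_elem, L = grid_desc.n_elem;
  std::vector<Moments> mo(nf);
  for (uword f = 0; f < nf; ++f) {
    Stats st = base;
    downdate(st, X.row(rows(f)), y(rows(f)));
    mo[f] = standardize(st);
  }
  mat Beta(p, nf, fill::zeros);
  vec sse(L, fill::zeros), beta(p);
  for (uword s = 0; s < L; ++s) {
    for (uword f = 0; f < nf; ++f) {
      beta = Beta.col(f);
      cd_solve(mo[f], grid_desc(s), beta, tol, maxit, nullptr);
      Beta.col(f) = beta;
      double e = y(rows(f)) - predict_one(mo[f], beta, X.row(rows(f)));
      sse(s) += e * e;
    }
  }
  return sse;
}

} // namespace

// Fit the lasso path for a vector of penalties (any order). Coefficients
// returned on the original predictor scale with unpenalized intercept.
// [[Rcpp::export]]
Rcpp::List cpp_lasso_path(const arma::mat& X, const arma::vec& y,
                          const arma::vec& lambdas,
                          double tol = 1e-7, int maxit = 100000,
                          bool trace_objective = false) {
  Stats st = full_stats(X, y);
  Moments mo = standardize(st);
  const uword p = X.n_cols, L = lambdas.n_elem;
  uvec ord = sort_index(lambdas, "descend");
  mat beta_std(p, L, fill::zeros), coef(p, L, fill::zeros);
  vec intercept(L, fill::zeros), sweeps(L, fill::zeros);
  vec beta(p, fill::zeros);
  std::vector<double> obj;
  for (uword s = 0; s < L; ++s) {
    uword idx = ord(s);
    sweeps(idx) = cd_solve(mo, lambdas(idx), beta, tol, maxit,
                           trace_objective ? &obj : nullptr);
    beta_std.col(idx) = beta;
    double ic = mo.ybar;
    for (uword j = 0; j < p; ++j) {
      if (mo.active(j) && beta(j) != 0.0) {
        coef(j, idx) = beta(j) / mo.sd(j);
        ic -= coef(j, idx) * mo.m(j);
      }
    }
    intercept(idx) = ic;
  }
  return Rcpp::List::create(
    Rcpp::Named("coef") = coef,
    Rcpp::Named("intercept") = intercept,
    Rcpp::Named("beta_std") = beta_std,
    Rcpp::Named("lambda") = lambdas,
    Rcpp::Named("lambda_max") = lambda_max(mo),
    Rcpp::Named("center") = mo.m,
    Rcpp::Named("scale") = mo.sd,
    Rcpp::Named("sweeps") = sweeps,
    Rcpp::Named("objective_trace") = obj);
}

// Leave-one-out CV error for each penalty in `lambdas` (grid fixed across
// folds; the model refit from scratch, via downdated statistics, per fold).
// [[Rcpp::export]]
arma::vec cpp_loocv_mse(const arma::mat& X, const arma::vec& y,
                        const arma::vec& lambdas,
                        double tol = 1e-7, int maxit = 100000) {
  Stats full = full_stats(X, y);
  const uword n = X.n_rows, L = lambdas.n_elem;
  uvec ord = sort_index(lambdas, "descend");
  uvec rows = regspace<uvec>(0, n - 1);
  vec sse_desc = loocv_grid_sse(full, X, y, rows, lambdas(ord), tol, maxit);
  vec mse(L);
  for (uword s = 0; s < L; ++s) mse(ord(s)) = sse_desc(s) / (double)n;
  return mse;
}

// Fully nested leave-one-out predictions: for each held-out row the
// penalty grid is rebuilt and the penalty re-selected by an inner LOOCV
// on the remaining n-1 rows (no information leakage). With nested =
// false, every outer fold refits at the supplied fixed lambda.
// [[Rcpp::export]]
Rcpp::List cpp_nested_loocv(const arma::mat& X, const arma::vec& y,
                            int nlambda = 100, double min_ratio = 1e-3,
                            double tol = 1e-7, int maxit = 100000,
                            bool nested = true, double lambda_fixed = 0.0) {
  Stats full = full_stats(X, y);
  const uword n = X.n_rows, p = X.n_cols;
  vec pred(n, fill::zeros), lam_used(n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    Stats st_i = full;
    downdate(st_i, X.row(i), y(i));
    Moments mo_i = standardize(st_i);
    double lam_star = lambda_fixed;
    if (nested) {
      vec grid = make_grid(lambda_max(mo_i), nlambda, min_ratio);
      uvec rows(n - 1);
      uword f = 0;
      for (uword j = 0; j < n; ++j) if (j != i) rows(f++) = j;
      vec sse = loocv_grid_sse(st_i, X, y, rows, grid, tol, maxit);
      // ties toward the larger penalty (sparser model); grid is decreasing
      uword best = 0;
      for (uword s = 1; s < grid.n_elem; ++s)
        if (sse(s) < sse(best) - 1e-12) best = s;
      lam_star = grid(best);
    }
    vec beta(p, fill::zeros);
    cd_solve(mo_i, lam_star, beta, tol, maxit, nullptr);
    pred(i) = predict_one(mo_i, beta, X.row(i));
    lam_used(i) = lam_star;
  }
  return Rcpp::List::create(Rcpp::Named("pred") = pred,
                            Rcpp::Named("lambda") = lam_used);
}
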