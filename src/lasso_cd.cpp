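#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

inline double soft(double z, double g) {
  return (z > g) ? z - g : ((z < -g) ? z + g : 0.0);
}

// Coordinate descent over a decreasing lambda grid on precomputed centered
// moments: C = X'X/n, b = X'y/n. Warm-started along the grid. Objective
// (1/2n)||y - Xb||^2 + lambda*||b||_1 is traced per sweep when requested.
static arma::mat cd_path_core(const arma::mat& C, const arma::vec& b,
                              const arma::vec& lambda, double tol,
                              int max_sweeps, double yvar,
                              std::vector< std::vector<double> >* obj_trace) {
  const int p = C.n_cols, L = lambda.n_elem;
  arma::mat betas(p, L, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec q(p, arma::fill::zeros);  // C * beta
  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double maxdelta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double cjj = C(j, j);
        const double rho = b[j] - q[j] + cjj * beta[j];
        const double bj = soft(rho, lam) / cjj;
        const double d = bj - beta[j];
        if (d != 0.0) {
          q += C.col(j) * d;
          beta[j] = bj;
          if (std::abs(d) > maxdelta) maxdelta = std::abs(d);
        }
      }
      if (obj_trace) {
        double obj = 0.5 * (yvar - 2.0 * arma::dot(b, beta) +
                            arma::dot(beta, q)) +
                     lam * arma::accu(arma::abs(beta));
        (*obj_trace)[l].push_back(obj);
      }
      if (maxdelta < tol) break;
    }
    betas.col(l) = beta;
  }
  return betas;
}

// [[Rcpp::export]]
List lasso_path_cpp(const arma::mat& X, const arma::vec& y,
                    const arma::vec& lambda, double tol, int max_sweeps,
                    bool trace) {
  const int n = X.n_rows;
  arma::rowvec xbar = arma::mean(X, 0);
  const double ybar = arma::mean(y);
  arma::mat Xc = X.each_row() - xbar;
  arma::vec yc = y - ybar;
  arma::mat C = (Xc.t() * Xc) / n;
  arma::vec b = (Xc.t() * yc) / n;
  const double yvar = arma::dot(yc, yc) / n;

  std::vector< std::vector<double> > tr;
  if (trace) tr.resize(lambda.n_elem);
  arma::mat betas = cd_path_core(C, b, lambda, tol, max_sweeps, yvar,
                                 trace ? &tr : nullptr);
  arma::rowvec intercept = ybar - xbar * betas;

  List out = List::create(_["beta"] = betas,
                          _["intercept"] = arma::vec(intercept.t()));
  if (trace) {
    List tl(tr.size());
    for (size_t l = 0; l < tr.size(); ++l) tl[l] = wrap(tr[l]);
    out["objective_trace"] = tl;
  }
  return out;
}

// Repeated k-fold CV with squared-error loss. `folds` is n_repeats x n with
// fold ids in 1..K; each repeat yields one CV error curve over lambda (mean
// squared held-out error pooled over folds), and curves are averaged.
// [[Rcpp::export]]
List lasso_cv_cpp(const arma::mat& X, const arma::vec& y,
                  const arma::vec& lambda, const IntegerMatrix& folds,
                  double tol, int max_sweeps) {
  const int n = X.n_rows, L = lambda.n_elem;
  const int n_rep = folds.nrow();
  const arma::mat S = X.t() * X;
  const arma::vec sxy = X.t() * y;
  const arma::rowvec cs = arma::sum(X, 0);
  const double ysum = arma::accu(y);

  arma::mat run_err(n_rep, L, arma::fill::zeros);
  for (int r = 0; r < n_rep; ++r) {
    int K = 0;
    for (int i = 0; i < n; ++i) if (folds(r, i) > K) K = folds(r, i);
    arma::mat sse(L, 1, arma::fill::zeros);
    arma::vec errL(L, arma::fill::zeros);
    for (int k = 1; k <= K; ++k) {
      std::vector<arma::uword> te;
      for (int i = 0; i < n; ++i) if (folds(r, i) == k) te.push_back(i);
      if (te.empty()) continue;
      arma::uvec idx(te.size());
      for (size_t i = 0; i < te.size(); ++i) idx[i] = te[i];
      arma::mat Xte = X.rows(idx);
      arma::vec yte = y.elem(idx);
      const int n_tr = n - (int)idx.n_elem;

      arma::mat Str = S - Xte.t() * Xte;
      arma::vec sxytr = sxy - Xte.t() * yte;
      arma::rowvec cstr = cs - arma::sum(Xte, 0);
      const double ybar = (ysum - arma::accu(yte)) / n_tr;
      arma::rowvec xbar = cstr / n_tr;
      arma::mat C = Str / n_tr - xbar.t() * xbar;
      arma::vec b = sxytr / n_tr - xbar.t() * ybar;

      arma::mat betas = cd_path_core(C, b, lambda, tol, max_sweeps, 0.0,
                                     nullptr);
      arma::rowvec intercept = ybar - xbar * betas;
      arma::mat pred = Xte * betas;          // n_te x L
      pred.each_row() += intercept;
      arma::mat resid = pred.each_col() - yte;
      errL += arma::sum(arma::square(resid), 0).t();
    }
    run_err.row(r) = (errL / n).t();
  }
  arma::rowvec mean_curve = arma::mean(run_err, 0);
  return List::create(_["cv_mean_error"] = arma::vec(mean_curve.t()),
                      _["run_error"] = run_err);
}
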