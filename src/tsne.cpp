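#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Exact (theta = 0) t-SNE: full N^2 input affinities via per-point binary
// search on the Gaussian bandwidth to hit the target perplexity, full
// gradient, momentum schedule with early exaggeration. Returns the embedding
// and the KL divergence trace.

static arma::mat squared_distances(const arma::mat& X) {
  arma::vec s = arma::sum(arma::square(X), 1);
  arma::mat D = arma::repmat(s, 1, X.n_rows) +
                arma::repmat(s.t(), X.n_rows, 1) - 2.0 * X * X.t();
  D.diag().zeros();
  D.transform([](double v) { return v < 0 ? 0.0 : v; });
  return D;
}

static arma::mat input_affinities(const arma::mat& D2, double perplexity) {
  const int n = D2.n_rows;
  const double log_perp = std::log(perplexity);
  arma::mat P(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, beta_lo = 0.0, beta_hi = arma::datum::inf;
    arma::rowvec Di = D2.row(i);
    arma::rowvec Pi(n);
    for (int it = 0; it < 200; ++it) {
      Pi = arma::exp(-Di * beta);
      Pi[i] = 0.0;
      double sumP = arma::accu(Pi);
      if (sumP <= 0) sumP = 1e-300;
      double H = std::log(sumP) + beta * arma::dot(Di, Pi) / sumP;
      double diff = H - log_perp;
      if (std::abs(diff) < 1e-7) break;
      if (diff > 0) {  // entropy too high -> narrow kernel
        beta_lo = beta;
        beta = std::isinf(beta_hi) ? beta * 2.0 : (beta + beta_hi) / 2.0;
      } else {
        beta_hi = beta;
        beta = (beta + beta_lo) / 2.0;
      }
    }
    P.row(i) = Pi / std::max(arma::accu(Pi), 1e-300);
  }
  P = (P + P.t()) / (2.0 * n);
  P.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  return P;
}

// [[Rcpp::export]]
List tsne_exact_cpp(const arma::mat& X, const arma::mat& Y0,
                    double perplexity, int max_iter, double eta,
                    double exaggeration, int exag_iters,
                    int momentum_switch, int kl_every) {
  const int n = X.n_rows;
  arma::mat P = input_affinities(squared_distances(X), perplexity);

  arma::mat Y = Y0;
  arma::mat dY(n, 2, arma::fill::zeros);
  arma::mat gains(n, 2, arma::fill::ones);
  std::vector<double> kl_trace;

  arma::mat Pwork = P * exaggeration;
  for (int iter = 1; iter <= max_iter; ++iter) {
    if (iter == exag_iters + 1) Pwork = P;
    const double momentum = (iter <= momentum_switch) ? 0.5 : 0.8;

    arma::mat D2y = squared_distances(Y);
    arma::mat num = 1.0 / (1.0 + D2y);  // unnormalized q
    num.diag().zeros();
    const double sumQ = std::max(arma::accu(num), 1e-300);

    arma::mat PQ = (Pwork - num / sumQ) % num;
    arma::mat grad(n, 2, arma::fill::zeros);
    arma::vec rs = arma::sum(PQ, 1);
    grad = 4.0 * (arma::diagmat(rs) * Y - PQ * Y);

    // adaptive gains as in the reference implementation
    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < 2; ++d) {
        const bool same = (grad(i, d) > 0) == (dY(i, d) > 0);
        gains(i, d) = same ? std::max(gains(i, d) * 0.8, 0.01)
                           : gains(i, d) + 0.2;
      }
    }
    dY = momentum * dY - eta * (gains % grad);
    Y += dY;
    Y.each_row() -= arma::mean(Y, 0);

    if (iter % kl_every == 0 || iter == max_iter) {
      arma::mat Q = num / sumQ;
      Q.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
      double kl = arma::accu(P % arma::log(P / Q));
      kl_trace.push_back(kl);
    }
  }
  return List::create(_["Y"] = Y, _["kl_trace"] = wrap(kl_trace));
}
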