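// Exact t-SNE, split so that input affinities (which depend only on the data
// and perplexity) can be computed once per run and shared across the many
// random restarts of the embedding ensemble.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

//' @noRd
// [[Rcpp::export]]
arma::mat tsne_affinities_cpp(const arma::mat& X, double perplexity, double tol = 1e-5) {
  const uword n = X.n_rows;
  vec ss = sum(square(X), 1);
  mat D = repmat(ss, 1, n) + repmat(ss.t(), n, 1) - 2.0 * (X * X.t());
  D.diag().zeros();
  D.transform([](double v) { return v < 0.0 ? 0.0 : v; });  // numerical guard

  mat P(n, n, fill::zeros);
  const double logU = std::log(perplexity);
  for (uword i = 0; i < n; ++i) {
    // binary search for the Gaussian precision giving the target perplexity
    double beta = 1.0, betamin = -datum::inf, betamax = datum::inf;
    rowvec Di = D.row(i);
    Di(i) = datum::inf;
    rowvec Pi(n, fill::zeros);
    for (int it = 0; it < 64; ++it) {
      Pi = exp(-Di * beta);
      Pi(i) = 0.0;
      double sumP = accu(Pi);
      if (sumP < 1e-300) sumP = 1e-300;
      double sumDP = 0.0;
      for (uword j = 0; j < n; ++j)
        if (j != i && Pi(j) > 0.0) sumDP += Di(j) * Pi(j);
      double H = std::log(sumP) + beta * sumDP / sumP;
      Pi /= sumP;
      double diff = H - logU;
      if (std::abs(diff) < tol) break;
      if (diff > 0) {
        betamin = beta;
        beta = std::isinf(betamax) ? beta * 2.0 : 0.5 * (beta + betamax);
      } else {
        betamax = beta;
        beta = std::isinf(betamin) ? beta * 0.5 : 0.5 * (beta + betamin);
      }
    }
    P.row(i) = Pi;
  }
  P += P.t();
  P /= accu(P);
  P.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  return P;
}

//' @noRd
// [[Rcpp::export]]
arma::mat tsne_gradient_cpp(const arma::mat& P, const arma::mat& Y0,
                            int max_iter = 500, double eta = 200.0,
                            double exaggeration = 12.0, int exag_iter = 100,
                            double mom_init = 0.5, double mom_final = 0.8,
                            int mom_switch = 250) {
  const int n = P.n_rows;
  std::vector<double> y1(n), y2(n), g1(n), g2(n), d1(n, 0.0), d2(n, 0.0),
      gain1(n, 1.0), gain2(n, 1.0), q(((size_t)n * (n - 1)) / 2);
  for (int i = 0; i < n; ++i) {
    y1[i] = Y0(i, 0);
    y2[i] = Y0(i, 1);
  }
  const double* Pm = P.memptr();
  for (int iter = 0; iter < max_iter; ++iter) {
    const double ex = (iter < exag_iter) ? exaggeration : 1.0;
    // pass 1: Student-t kernel over all pairs and its normalizer
    double sumQ = 0.0;
    size_t idx = 0;
    for (int i = 0; i < n; ++i) {
      const double yi1 = y1[i], yi2 = y2[i];
      for (int j = i + 1; j < n; ++j, ++idx) {
        const double dx = yi1 - y1[j], dy = yi2 - y2[j];
        const double qq = 1.0 / (1.0 + dx * dx + dy * dy);
        q[idx] = qq;
        sumQ += qq;
      }
    }
    sumQ *= 2.0;
    const double inv_sumQ = 1.0 / sumQ;
    // pass 2: KL gradient, exploiting pair symmetry
    std::fill(g1.begin(), g1.end(), 0.0);
    std::fill(g2.begin(), g2.end(), 0.0);
    idx = 0;
    for (int i = 0; i < n; ++i) {
      const double yi1 = y1[i], yi2 = y2[i];
      double gi1 = 0.0, gi2 = 0.0;
      const double* Pcol = Pm + (size_t)i * n;  // symmetric, col == row
      for (int j = i + 1; j < n; ++j, ++idx) {
        const double qq = q[idx];
        const double c = 4.0 * (ex * Pcol[j] - qq * inv_sumQ) * qq;
        const double fx = c * (yi1 - y1[j]), fy = c * (yi2 - y2[j]);
        gi1 += fx;
        gi2 += fy;
        g1[j] -= fx;
        g2[j] -= fy;
      }
      g1[i] += gi1;
      g2[i] += gi2;
    }
    // momentum with the usual sign-adaptive per-coordinate gains
    const double mom = (iter < mom_switch) ? mom_init : mom_final;
    double m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < n; ++i) {
      gain1[i] = (std::signbit(g1[i]) != std::signbit(d1[i])) ? gain1[i] + 0.2
                                                              : gain1[i] * 0.8;
      gain2[i] = (std::signbit(g2[i]) != std::signbit(d2[i])) ? gain2[i] + 0.2
                                                              : gain2[i] * 0.8;
      if (gain1[i] < 0.01) gain1[i] = 0.01;
      if (gain2[i] < 0.01) gain2[i] = 0.01;
      d1[i] = mom * d1[i] - eta * gain1[i] * g1[i];
      d2[i] = mom * d2[i] - eta * gain2[i] * g2[i];
      y1[i] += d1[i];
      y2[i] += d2[i];
      m1 += y1[i];
      m2 += y2[i];
    }
    m1 /= n;
    m2 /= n;
    for (int i = 0; i < n; ++i) {
      y1[i] -= m1;
      y2[i] -= m2;
    }
  }
  mat Y(n, 2);
  for (int i = 0; i < n; ++i) {
    Y(i, 0) = y1[i];
    Y(i, 1) = y2[i];
  }
  return Y;
}
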