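// Conjugate Gibbs samplers for the normal-distribution-model (NORM) and
// normal-regression-model (NRM) imputation fits. Both use R's RNG so chains
// are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Draw sigma2 ~ IG(shape, rate) via 1/Gamma(shape, rate).
static inline double rinvgamma(double shape, double rate) {
    return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// NORM: x_1..x_n iid N(mu, sigma2) under Jeffreys prior 1/sigma2.
// Alternates sigma2 | mu ~ IG(n/2, n * Vmu / 2) with Vmu = mean((x - mu)^2),
// and mu | sigma2 ~ N(xbar, sigma2 / n). Chain initialized at the MLEs.
// Returns post-burn-in means of mu and sigma2.
// [[Rcpp::export]]
List gibbs_norm_cpp(const arma::vec& x, int n_samples, int burn) {
    const int n = x.n_elem;
    const double xbar = arma::mean(x);
    double mu = xbar;
    double sigma2 = arma::mean(arma::square(x - xbar));
    if (sigma2 <= 0.0) sigma2 = 1e-12;
    double sum_mu = 0.0, sum_s2 = 0.0;
    int kept = 0;
    for (int t = 0; t < n_samples; ++t) {
        const double vmu = arma::mean(arma::square(x - mu));
        sigma2 = rinvgamma(0.5 * n, 0.5 * n * vmu);
        mu = R::rnorm(xbar, std::sqrt(sigma2 / n));
        if (t >= burn) { sum_mu += mu; sum_s2 += sigma2; ++kept; }
    }
    return List::create(_["mu"] = sum_mu / kept,
                        _["sigma2"] = sum_s2 / kept);
}

// NRM: y ~ N(X beta, sigma2 I) with priors beta ~ N(0, tau2 I) and
// sigma2 ~ IG(nu0/2, S0/2). Conditionals:
//   sigma2 | beta ~ IG((nu0 + n)/2, (RSS + S0)/2)
//   beta | sigma2 ~ N(A, B), B^{-1} = X'X/sigma2 + I/tau2,
//                    A = B X'y / sigma2.
// X'X is eigendecomposed once so each beta draw costs two dense
// matrix-vector products instead of a Cholesky factorization.
// Returns post-burn-in means of beta and sigma2.
// [[Rcpp::export]]
List gibbs_reg_cpp(const arma::vec& y, const arma::mat& X, double tau2,
                   double nu0, double S0, int n_samples, int burn) {
    const int n = y.n_elem;
    const int N = X.n_cols;
    arma::mat XtX = X.t() * X;
    arma::vec Xty = X.t() * y;
    arma::vec d;
    arma::mat V;
    arma::eig_sym(d, V, XtX);
    d.for_each([](double& v) { if (v < 0.0) v = 0.0; });
    const arma::vec VtXty = V.t() * Xty;
    double sigma2 = 1.0;  // prior mean of sigma2 under (nu0, S0) = (4, 2)
    arma::vec beta(N, arma::fill::zeros);
    arma::vec beta_sum(N, arma::fill::zeros);
    double s2_sum = 0.0;
    int kept = 0;
    arma::vec z(N), w(N), m(N), r(n);
    for (int t = 0; t < n_samples; ++t) {
        w = 1.0 / (d / sigma2 + 1.0 / tau2);
        m = V * (w % VtXty / sigma2);
        for (int p = 0; p < N; ++p) z[p] = R::norm_rand();
        beta = m + V * (arma::sqrt(w) % z);
        r = y - X * beta;
        const double rss = arma::dot(r, r);
        sigma2 = rinvgamma(0.5 * (nu0 + n), 0.5 * (rss + S0));
        if (t >= burn) { beta_sum += beta; s2_sum += sigma2; ++kept; }
    }
    beta_sum /= kept;
    return List::create(_["beta"] = NumericVector(beta_sum.begin(), beta_sum.end()),
                        _["sigma2"] = s2_sum / kept,
                        _["kept"] = kept);
}
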