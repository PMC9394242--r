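#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mixture log-likelihood: sum log(lam * N(x; mu, sigma) + (1 - lam) * cdens).
static double mix_loglik(const double* x, const double* cdens, int n,
                         double mu, double sigma, double lam) {
  const double norm_c = 1.0 / (sigma * 2.5066282746310002); // sqrt(2*pi)
  const double q = 1.0 - lam;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double z = (x[i] - mu) / sigma;
    double f = lam * norm_c * std::exp(-0.5 * z * z) + q * cdens[i];
    ll += std::log(f > 1e-320 ? f : 1e-320);
  }
  return ll;
}

// Negative KS distance between the mixture CDF and the ECDF of x (x sorted
// ascending, ccdf = contamination CDF at the sorted x). Larger is better.
static double neg_ks_distance(const double* x, const double* ccdf, int n,
                              double mu, double sigma, double lam) {
  double d = 0.0;
  const double q = 1.0 - lam;
  for (int i = 0; i < n; ++i) {
    double f = lam * R::pnorm(x[i], mu, sigma, 1, 0) + q * ccdf[i];
    double lo = (double)i / n, hi = (double)(i + 1) / n;
    double di = std::max(std::fabs(f - lo), std::fabs(f - hi));
    if (di > d) d = di;
  }
  return -d;
}

// Iterative stochastic parameter-vector search. Per iteration, vector_size
// candidate values are drawn for each of mu, sigma, lambda uniformly around
// the current best; the i-th values form a candidate triple scored by the
// objective; the best triple is kept and the search ranges shrink by a
// constant factor. Uses R's RNG, so set.seed() makes it reproducible.
// [[Rcpp::export]]
List stochastic_search_cpp(NumericVector x, NumericVector cdens,
                           NumericVector ccdf,
                           double mu0, double sigma0, double lam0,
                           int n_iterations, int vector_size, double shrink,
                           double w_mu, double w_sigma, double w_lam,
                           bool use_ks) {
  const int n = x.size();
  const double* px = x.begin();
  const double* pc = cdens.begin();
  const double* pf = ccdf.begin();

  double best_mu = mu0, best_sigma = sigma0, best_lam = lam0;
  double best_obj = use_ks ? neg_ks_distance(px, pf, n, mu0, sigma0, lam0)
                           : mix_loglik(px, pc, n, mu0, sigma0, lam0);

  NumericMatrix trace(n_iterations, 8);
  for (int it = 0; it < n_iterations; ++it) {
    if (it % 128 == 0) Rcpp::checkUserInterrupt();
    const double cm0 = best_mu, cs0 = best_sigma, cl0 = best_lam;
    double it_mu = best_mu, it_sigma = best_sigma, it_lam = best_lam;
    double it_obj = best_obj;
    for (int j = 0; j < vector_size; ++j) {
      double cm = R::runif(cm0 - w_mu, cm0 + w_mu);
      double cs = R::runif(cs0 - w_sigma, cs0 + w_sigma);
      double cl = R::runif(cl0 - w_lam, cl0 + w_lam);
      if (cm < 1e-8) cm = 1e-8;
      if (cs < 1e-6) cs = 1e-6;
      if (cl < 0.01) cl = 0.01;
      if (cl > 1.0)  cl = 1.0;
      double obj = use_ks ? neg_ks_distance(px, pf, n, cm, cs, cl)
                          : mix_loglik(px, pc, n, cm, cs, cl);
      if (obj > it_obj) { it_obj = obj; it_mu = cm; it_sigma = cs; it_lam = cl; }
    }
    best_mu = it_mu; best_sigma = it_sigma; best_lam = it_lam; best_obj = it_obj;
    w_mu *= shrink; w_sigma *= shrink; w_lam *= shrink;
    trace(it, 0) = it + 1;
    trace(it, 1) = best_mu;
    trace(it, 2) = best_sigma;
    trace(it, 3) = best_lam;
    trace(it, 4) = best_obj;
    trace(it, 5) = w_mu;
    trace(it, 6) = w_sigma;
    trace(it, 7) = w_lam;
  }
  return List::create(_["mu"] = best_mu, _["sigma"] = best_sigma,
                      _["lam"] = best_lam, _["objective"] = best_obj,
                      _["trace"] = trace);
}
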