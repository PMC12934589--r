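#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA on a document-term matrix.
//
// Full conditional for a token's topic assignment:
//   P(z = k | .) propto (n_dk + alpha) * (n_kw + eta) / (n_k + V * eta)
// beta and gamma are posterior-mean estimates from the final state.
// RNG is a private mt19937_64 stream seeded from `seed`, so fits are exactly
// reproducible and independent of R's global RNG.
// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(IntegerMatrix dtm, int K, double alpha, double eta,
                   int iterations, int burn_in, int thin, int seed) {
  const int D = dtm.nrow();
  const int V = dtm.ncol();

  // expand the matrix into a token stream
  long total = 0;
  for (int d = 0; d < D; ++d)
    for (int w = 0; w < V; ++w) total += dtm(d, w);
  if (total < K) stop("K exceeds the total token count");

  std::vector<int> tok_d(total), tok_w(total), z(total);
  {
    long t = 0;
    for (int d = 0; d < D; ++d)
      for (int w = 0; w < V; ++w)
        for (int c = 0; c < dtm(d, w); ++c) { tok_d[t] = d; tok_w[t] = w; ++t; }
  }

  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  std::vector<long> n_dk(static_cast<long>(D) * K, 0),
                    n_kw(static_cast<long>(K) * V, 0),
                    n_k(K, 0), n_d(D, 0);
  for (long t = 0; t < total; ++t) {
    int k = static_cast<int>(runif(rng) * K);
    if (k == K) k = K - 1;
    z[t] = k;
    ++n_dk[static_cast<long>(tok_d[t]) * K + k];
    ++n_kw[static_cast<long>(k) * V + tok_w[t]];
    ++n_k[k];
    ++n_d[tok_d[t]];
  }

  const double Veta = V * eta;
  std::vector<double> p(K);
  std::vector<double> trace;

  auto loglik = [&]() {
    double ll = K * (std::lgamma(Veta) - V * std::lgamma(eta));
    for (int k = 0; k < K; ++k) {
      for (int w = 0; w < V; ++w)
        ll += std::lgamma(n_kw[static_cast<long>(k) * V + w] + eta);
      ll -= std::lgamma(n_k[k] + Veta);
    }
    ll += D * (std::lgamma(K * alpha) - K * std::lgamma(alpha));
    for (int d = 0; d < D; ++d) {
      for (int k = 0; k < K; ++k)
        ll += std::lgamma(n_dk[static_cast<long>(d) * K + k] + alpha);
      ll -= std::lgamma(n_d[d] + K * alpha);
    }
    return ll;
  };

  for (int iter = 1; iter <= iterations; ++iter) {
    for (long t = 0; t < total; ++t) {
      const int d = tok_d[t], w = tok_w[t], old = z[t];
      --n_dk[static_cast<long>(d) * K + old];
      --n_kw[static_cast<long>(old) * V + w];
      --n_k[old];
      double cum = 0.0;
      for (int k = 0; k < K; ++k) {
        cum += (n_dk[static_cast<long>(d) * K + k] + alpha) *
               (n_kw[static_cast<long>(k) * V + w] + eta) /
               (n_k[k] + Veta);
        p[k] = cum;
      }
      const double u = runif(rng) * cum;
      int k_new = 0;
      while (k_new < K - 1 && p[k_new] < u) ++k_new;
      z[t] = k_new;
      ++n_dk[static_cast<long>(d) * K + k_new];
      ++n_kw[static_cast<long>(k_new) * V + w];
      ++n_k[k_new];
    }
    if (iter > burn_in && (iter - burn_in) % thin == 0)
      trace.push_back(loglik());
  }

  NumericMatrix beta(K, V), gamma(D, K);
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < V; ++w)
      beta(k, w) = (n_kw[static_cast<long>(k) * V + w] + eta) / (n_k[k] + Veta);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k)
      gamma(d, k) = (n_dk[static_cast<long>(d) * K + k] + alpha) /
                    (n_d[d] + K * alpha);

  return List::create(_["beta"] = beta, _["gamma"] = gamma,
                      _["loglik_trace"] = NumericVector(trace.begin(),
                                                        trace.end()));
}
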