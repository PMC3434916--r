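// Gibbs sampler for the admixture model with uncorrelated allele frequencies
// (Pritchard-Stephens-Donnelly): latent origin per allele copy, Dirichlet
// frequency and ancestry updates, Metropolis update of the common alpha.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::mt19937_64 RNG;

static inline double rgamma1(RNG& g, double shape) {
  std::gamma_distribution<double> d(shape, 1.0);
  return d(g);
}
static inline double runif1(RNG& g) {
  std::uniform_real_distribution<double> d(0.0, 1.0);
  return d(g);
}
static inline double rnorm1(RNG& g, double mu, double sd) {
  std::normal_distribution<double> d(mu, sd);
  return d(g);
}

// geno: N x 2L matrix of 0-based allele codes (columns l*2, l*2+1 per locus)
// [[Rcpp::export]]
List cpp_structure_gibbs(IntegerMatrix geno, IntegerVector n_alleles, int K,
                         int burnin, int reps, double lambda, double alpha0,
                         double alphamax, double alphapropsd, int seed) {
  RNG g(seed);
  int N = geno.nrow();
  int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("geno must have 2 columns per locus");
  int Jmax = 0;
  for (int l = 0; l < L; ++l) Jmax = std::max(Jmax, (int)n_alleles[l]);

  std::vector<int> Z(N * 2 * L);
  for (size_t i = 0; i < Z.size(); ++i) Z[i] = (int)(runif1(g) * K);
  std::vector<double> P(K * L * Jmax, 0.0);   // P[k][l][j]
  std::vector<double> Q(N * K, 1.0 / K);
  double alpha = alpha0;

  std::vector<double> qsum(N * K, 0.0);
  std::vector<double> lnl_trace;
  std::vector<double> alpha_trace;
  lnl_trace.reserve(reps);
  std::vector<double> cnt(Jmax), probs(K), qcnt(K);

  int total = burnin + reps;
  for (int it = 0; it < total; ++it) {
    // P update
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        int J = n_alleles[l];
        for (int j = 0; j < J; ++j) cnt[j] = lambda;
        for (int i = 0; i < N; ++i) {
          for (int c = 0; c < 2; ++c) {
            int idx = (i * 2 + c) * L + l;
            if (Z[idx] == k) cnt[geno(i, 2 * l + c)] += 1.0;
          }
        }
        double s = 0;
        double* pk = &P[(k * L + l) * Jmax];
        for (int j = 0; j < J; ++j) { pk[j] = rgamma1(g, cnt[j]); s += pk[j]; }
        for (int j = 0; j < J; ++j) pk[j] /= s;
      }
    }
    // Q update
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < K; ++k) qcnt[k] = alpha;
      for (int c = 0; c < 2; ++c)
        for (int l = 0; l < L; ++l) qcnt[Z[(i * 2 + c) * L + l]] += 1.0;
      double s = 0;
      for (int k = 0; k < K; ++k) { Q[i * K + k] = rgamma1(g, qcnt[k]); s += Q[i * K + k]; }
      for (int k = 0; k < K; ++k) Q[i * K + k] /= s;
    }
    // Z update
    for (int i = 0; i < N; ++i) {
      for (int c = 0; c < 2; ++c) {
        for (int l = 0; l < L; ++l) {
          int j = geno(i, 2 * l + c);
          double s = 0;
          for (int k = 0; k < K; ++k) {
            probs[k] = Q[i * K + k] * P[(k * L + l) * Jmax + j];
            s += probs[k];
          }
          double u = runif1(g) * s, acc = 0;
          int pick = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += probs[k];
            if (u <= acc) { pick = k; break; }
          }
          Z[(i * 2 + c) * L + l] = pick;
        }
      }
    }
    // alpha Metropolis (uniform prior on (0, alphamax])
    if (K > 1) {
      double ap = rnorm1(g, alpha, alphapropsd);
      if (ap > 0 && ap <= alphamax) {
        double sumlq = 0;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k) sumlq += std::log(Q[i * K + k]);
        double lr = N * ((lgamma(K * ap) - K * lgamma(ap)) -
                         (lgamma(K * alpha) - K * lgamma(alpha))) +
                    (ap - alpha) * sumlq;
        if (std::log(runif1(g)) < lr) alpha = ap;
      }
    }
    if (it >= burnin) {
      for (size_t i = 0; i < qsum.size(); ++i) qsum[i] += Q[i];
      double lnl = 0;
      for (int i = 0; i < N; ++i) {
        for (int c = 0; c < 2; ++c) {
          for (int l = 0; l < L; ++l) {
            int j = geno(i, 2 * l + c);
            double s = 0;
            for (int k = 0; k < K; ++k)
              s += Q[i * K + k] * P[(k * L + l) * Jmax + j];
            lnl += std::log(s);
          }
        }
      }
      lnl_trace.push_back(lnl);
      if ((it - burnin) % 50 == 0) alpha_trace.push_back(alpha);
    }
  }
  NumericMatrix Qm(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Qm(i, k) = qsum[i * K + k] / reps;
  double m = 0, v = 0;
  for (double x : lnl_trace) m += x;
  m /= lnl_trace.size();
  for (double x : lnl_trace) v += (x - m) * (x - m);
  v /= (lnl_trace.size() - 1.0);
  return List::create(_["Q"] = Qm, _["lnP"] = m - v / 2.0, _["mean_lnL"] = m,
                      _["var_lnL"] = v, _["alpha"] = NumericVector(alpha_trace.begin(), alpha_trace.end()),
                      _["lnL"] = NumericVector(lnl_trace.begin(), lnl_trace.end()));
}
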