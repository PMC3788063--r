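// Gibbs sampler for the no-admixture-prior-free ("admixture model")
// Bayesian clustering of multilocus codominant genotypes:
//   Z  allele-copy origins            (categorical, collapsed each sweep)
//   P  cluster allele frequencies     (independent Dirichlet(1) prior)
//   Q  individual ancestry fractions  (symmetric Dirichlet(alpha) prior)
//   alpha shared across clusters, Metropolis random-walk update with a
//   uniform prior on (0, alpha_max].
// All randomness goes through R's RNG so runs are reproducible from
// set.seed() on the calling side.
#include <Rcpp.h>
using namespace Rcpp;

static inline int sample_cat(const double *w, int K, double tot) {
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix a1, IntegerMatrix a2,
                         IntegerVector n_alleles, int K,
                         int burnin, int reps,
                         double alpha_init, double alpha_max,
                         double alpha_sd) {
  const int n = a1.nrow(), L = a1.ncol();
  int maxA = 0;
  for (int l = 0; l < L; ++l) if (n_alleles[l] > maxA) maxA = n_alleles[l];
  // P[k + K*(a + maxA*l)]
  std::vector<double> P((size_t)K * maxA * L);
  std::vector<double> CP((size_t)K * maxA * L);
  NumericMatrix Q(n, K), Qsum(n, K);
  std::vector<double> CQ((size_t)n * K);
  for (int l = 0; l < L; ++l)
    for (int a = 0; a < n_alleles[l]; ++a)
      for (int k = 0; k < K; ++k)
        P[k + (size_t)K * (a + (size_t)maxA * l)] = 1.0 / n_alleles[l];
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;

  double alpha = alpha_init;
  int total = burnin + reps, accept = 0, proposals = 0;
  NumericVector lnl_trace(reps), alpha_trace(reps);
  std::vector<double> w(K);

  for (int it = 0; it < total; ++it) {
    std::fill(CP.begin(), CP.end(), 0.0);
    std::fill(CQ.begin(), CQ.end(), 0.0);
    // -- sample Z and collect counts --
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int copy = 0; copy < 2; ++copy) {
          int a = copy == 0 ? a1(i, l) : a2(i, l);
          if (a < 0) continue;
          double tot = 0.0;
          size_t base = (size_t)K * (a + (size_t)maxA * l);
          for (int k = 0; k < K; ++k) {
            w[k] = Q(i, k) * P[k + base];
            tot += w[k];
          }
          int k = sample_cat(w.data(), K, tot);
          CP[k + base] += 1.0;
          CQ[i + (size_t)n * k] += 1.0;
        }
      }
    }
    // -- sample P | Z  ~ Dirichlet(1 + counts) --
    for (int l = 0; l < L; ++l)
      for (int k = 0; k < K; ++k) {
        double tot = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          size_t idx = k + (size_t)K * (a + (size_t)maxA * l);
          double g = R::rgamma(1.0 + CP[idx], 1.0);
          P[idx] = g;
          tot += g;
        }
        for (int a = 0; a < n_alleles[l]; ++a)
          P[k + (size_t)K * (a + (size_t)maxA * l)] /= tot;
      }
    // -- sample Q | Z  ~ Dirichlet(alpha + counts) --
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + CQ[i + (size_t)n * k], 1.0);
        if (g < 1e-300) g = 1e-300;  // guard tiny-shape underflow
        Q(i, k) = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= tot;
    }
    // -- Metropolis update of alpha --
    if (K > 1) {
      double ap = alpha + norm_rand() * alpha_sd;
      ++proposals;
      if (ap > 0.0 && ap <= alpha_max) {
        double slogq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) slogq += std::log(Q(i, k));
        double lr = n * (R::lgammafn(K * ap) - K * R::lgammafn(ap)
                         - R::lgammafn(K * alpha)
                         + K * R::lgammafn(alpha))
          + (ap - alpha) * slogq;
        if (std::log(unif_rand()) < lr) { alpha = ap; ++accept; }
      }
    }
    // -- log-likelihood of the data under current (P, Q) --
    double lnl = 0.0;
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l)
        for (int copy = 0; copy < 2; ++copy) {
          int a = copy == 0 ? a1(i, l) : a2(i, l);
          if (a < 0) continue;
          double s = 0.0;
          size_t base = (size_t)K * (a + (size_t)maxA * l);
          for (int k = 0; k < K; ++k) s += Q(i, k) * P[k + base];
          lnl += std::log(s);
        }
    if (it >= burnin) {
      int j = it - burnin;
      lnl_trace[j] = lnl;
      alpha_trace[j] = alpha;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= reps;
  return List::create(
    _["Q"] = Qsum, _["lnl_trace"] = lnl_trace,
    _["alpha_trace"] = alpha_trace,
    _["accept_rate"] = proposals ? (double)accept / proposals : NA_REAL);
}
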