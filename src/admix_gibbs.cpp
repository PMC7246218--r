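#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the basic admixture model with uncorrelated
// allele-frequency prior.  Alleles are recoded 1..A_l per locus, 0 = missing.
// Updates: cluster allele frequencies P | Z ~ Dirichlet(lambda + counts);
// individual ancestry Q | Z ~ Dirichlet(alpha + origin counts); allele-origin
// labels Z | (P, Q); alpha (shared scalar) by random-walk Metropolis on a
// uniform (0, 10] prior.  Z is never stored: its sufficient statistics (the
// count arrays) are accumulated during the Z sweep.  The recorded data
// log-likelihood is log P(X | P, Q) = sum log( sum_k q_ik p_kla ).
//
// Memory layout: P and cnt are indexed [(offset[l] + a) * K + k] so the
// inner loops over k touch contiguous memory.
// [[Rcpp::export]]
List admix_gibbs_cpp(IntegerMatrix a1, IntegerMatrix a2,
                     IntegerVector n_alleles, int K,
                     double lambda, double alpha_init, double alpha_sd,
                     bool infer_alpha, int burnin, int iters, int thin) {
  const int n = a1.nrow(), L = a1.ncol();
  std::vector<int> offset(L + 1, 0);
  for (int l = 0; l < L; ++l) offset[l + 1] = offset[l] + n_alleles[l];
  const int totA = offset[L];

  // flat copies of the genotype matrices (column-major, as in R)
  std::vector<int> g1(a1.begin(), a1.end()), g2(a2.begin(), a2.end());

  std::vector<double> P((size_t)totA * K);
  std::vector<double> cnt((size_t)totA * K, 0.0);
  std::vector<double> m((size_t)n * K, 0.0);
  NumericMatrix Q(n, K);
  std::vector<double> qrow(K), w(K);
  double alpha = alpha_init;

  // initialize sufficient statistics by random origin assignment
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      for (int copy = 0; copy < 2; ++copy) {
        int a = copy == 0 ? g1[(size_t)l * n + i] : g2[(size_t)l * n + i];
        if (a <= 0) continue;
        int k = (int)(unif_rand() * K); if (k >= K) k = K - 1;
        cnt[(size_t)(offset[l] + a - 1) * K + k] += 1.0;
        m[(size_t)i * K + k] += 1.0;
      }
    }

  const int total_iter = burnin + iters;
  const int n_rec = iters / thin;
  NumericVector alpha_trace(n_rec), lnl_trace(n_rec);
  NumericMatrix qsum(n, K);
  int rec = 0;
  double lnl_s1 = 0.0, lnl_s2 = 0.0; // running sums over ALL post-burnin sweeps

  for (int it = 0; it < total_iter; ++it) {
    // P | counts
    for (int l = 0; l < L; ++l) {
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          double gdraw = R::rgamma(lambda + cnt[(size_t)(offset[l] + a) * K + k], 1.0);
          if (gdraw < 1e-300) gdraw = 1e-300;
          P[(size_t)(offset[l] + a) * K + k] = gdraw;
          s += gdraw;
        }
        for (int a = 0; a < n_alleles[l]; ++a)
          P[(size_t)(offset[l] + a) * K + k] /= s;
      }
    }

    // Q | origin counts
    double sumlogq = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double gdraw = R::rgamma(alpha + m[(size_t)i * K + k], 1.0);
        if (gdraw < 1e-300) gdraw = 1e-300;
        qrow[k] = gdraw; s += gdraw;
      }
      for (int k = 0; k < K; ++k) {
        double v = qrow[k] / s;
        if (v < 1e-300) v = 1e-300;
        Q(i, k) = v;
        sumlogq += std::log(v);
      }
    }

    // Z | (P, Q): sample origins, rebuild count arrays, accumulate lnL
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(m.begin(), m.end(), 0.0);
    double lnl = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) qrow[k] = Q(i, k);
      double *mi = &m[(size_t)i * K];
      for (int l = 0; l < L; ++l) {
        for (int copy = 0; copy < 2; ++copy) {
          int a = copy == 0 ? g1[(size_t)l * n + i] : g2[(size_t)l * n + i];
          if (a <= 0) continue;
          double *pa = &P[(size_t)(offset[l] + a - 1) * K];
          double tot = 0.0;
          for (int k = 0; k < K; ++k) { w[k] = qrow[k] * pa[k]; tot += w[k]; }
          lnl += std::log(tot);
          double u = unif_rand() * tot, acc = 0.0;
          int pick = K - 1;
          for (int k = 0; k < K; ++k) { acc += w[k]; if (u <= acc) { pick = k; break; } }
          cnt[(size_t)(offset[l] + a - 1) * K + pick] += 1.0;
          mi[pick] += 1.0;
        }
      }
    }

    // alpha | Q (random-walk Metropolis, uniform prior on (0, 10])
    if (infer_alpha && K > 1) {
      double prop = alpha + norm_rand() * alpha_sd;
      if (prop > 0.0 && prop <= 10.0) {
        double lr = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop))
                  - n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha))
                  + (prop - alpha) * sumlogq;
        if (lr >= 0.0 || unif_rand() < std::exp(lr)) alpha = prop;
      }
    }

    if (it >= burnin) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) qsum(i, k) += Q(i, k);
      lnl_s1 += lnl; lnl_s2 += lnl * lnl;
      int post = it - burnin;
      if ((post + 1) % thin == 0 && rec < n_rec) {
        alpha_trace[rec] = alpha;
        lnl_trace[rec] = lnl;
        ++rec;
      }
    }
  }
  double lnl_mean = lnl_s1 / iters;
  double lnl_var = iters > 1 ?
    (lnl_s2 - lnl_s1 * lnl_s1 / iters) / (iters - 1) : 0.0;

  NumericMatrix qmean(n, K);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += qsum(i, k);
    for (int k = 0; k < K; ++k) qmean(i, k) = qsum(i, k) / s;
  }
  return List::create(_["q"] = qmean, _["alpha_trace"] = alpha_trace,
                      _["lnl_trace"] = lnl_trace,
                      _["lnl_mean"] = lnl_mean, _["lnl_var"] = lnl_var);
}

// Markov-chain exact HWE test: explicit vector of 2N allele slots paired
// consecutively; the uniform distribution over slot arrangements induces
// the Levene conditional distribution on genotype arrays, so random slot
// swaps are always accepted.  The probability-ordering p-value is
// estimated per batch as the fraction of visited arrays whose conditional
// probability is <= that of the observed array.
// [[Rcpp::export]]
List hwe_mc_chain(IntegerVector g1, IntegerVector g2, int A,
                  int dememorization, int batches, int iterations_per_batch) {
  const int N = g1.size();
  std::vector<int> slot(2 * N);
  for (int i = 0; i < N; ++i) { slot[2 * i] = g1[i] - 1; slot[2 * i + 1] = g2[i] - 1; }

  // genotype counts (unordered pairs) and log weight 2^H / prod n_ij!
  std::vector<double> cntm((size_t)A * A, 0.0);
  auto idx = [A](int a, int b) { int hi = a > b ? a : b, lo = a > b ? b : a;
                                 return (size_t)hi * A + lo; };
  int H = 0;
  for (int i = 0; i < N; ++i) {
    cntm[idx(slot[2 * i], slot[2 * i + 1])] += 1.0;
    if (slot[2 * i] != slot[2 * i + 1]) ++H;
  }
  double logw = H * std::log(2.0);
  for (size_t c = 0; c < cntm.size(); ++c) logw -= R::lgammafn(cntm[c] + 1.0);
  const double logw_obs = logw;

  auto step = [&]() {
    int s1 = (int)(unif_rand() * 2 * N); if (s1 >= 2 * N) s1 = 2 * N - 1;
    int s2 = (int)(unif_rand() * 2 * N); if (s2 >= 2 * N) s2 = 2 * N - 1;
    if (s1 == s2) return;
    int p1 = s1 / 2, p2 = s2 / 2;
    if (p1 == p2) return; // same pair: genotype unchanged
    int a1o = slot[2 * p1], b1o = slot[2 * p1 + 1];
    int a2o = slot[2 * p2], b2o = slot[2 * p2 + 1];
    // remove old pairs
    cntm[idx(a1o, b1o)] -= 1.0; logw += std::log(cntm[idx(a1o, b1o)] + 1.0);
    if (a1o != b1o) { --H; logw -= std::log(2.0); }
    cntm[idx(a2o, b2o)] -= 1.0; logw += std::log(cntm[idx(a2o, b2o)] + 1.0);
    if (a2o != b2o) { --H; logw -= std::log(2.0); }
    std::swap(slot[s1], slot[s2]);
    int a1n = slot[2 * p1], b1n = slot[2 * p1 + 1];
    int a2n = slot[2 * p2], b2n = slot[2 * p2 + 1];
    cntm[idx(a1n, b1n)] += 1.0; logw -= std::log(cntm[idx(a1n, b1n)]);
    if (a1n != b1n) { ++H; logw += std::log(2.0); }
    cntm[idx(a2n, b2n)] += 1.0; logw -= std::log(cntm[idx(a2n, b2n)]);
    if (a2n != b2n) { ++H; logw += std::log(2.0); }
  };

  for (int i = 0; i < dememorization; ++i) step();
  NumericVector batch_p(batches);
  for (int b = 0; b < batches; ++b) {
    int hits = 0;
    for (int i = 0; i < iterations_per_batch; ++i) {
      step();
      if (logw <= logw_obs + 1e-9) ++hits;
    }
    batch_p[b] = (double)hits / iterations_per_batch;
  }
  return List::create(_["batch_p"] = batch_p);
}
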