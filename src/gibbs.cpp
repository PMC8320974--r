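#include <Rcpp.h>
using namespace Rcpp;

// Admixture-model Gibbs sampler for codominant genotypes with independent
// per-cluster allele frequencies (Dirichlet(lambda) prior), per-individual
// membership vectors Q ~ Dirichlet(alpha), and a Metropolis step on the
// common alpha with a uniform(0, alpha_max) prior. Uses R's RNG so runs are
// reproducible under set.seed().

static inline double rgamma_pos(double shape) {
  double g = R::rgamma(shape, 1.0);
  if (g <= 0.0) g = 1e-300;
  return g;
}

static void dirichlet_draw(const std::vector<double>& shape, std::vector<double>& out) {
  double s = 0.0;
  const int k = shape.size();
  for (int i = 0; i < k; ++i) { out[i] = rgamma_pos(shape[i]); s += out[i]; }
  for (int i = 0; i < k; ++i) out[i] /= s;
}

// [[Rcpp::export(name = ".gibbs_admixture_cpp")]]
List gibbs_admixture_cpp(IntegerMatrix A1, IntegerMatrix A2,
                         IntegerVector nAlleles, int K,
                         int burnin, int nsweeps,
                         double lambda, double alpha_init,
                         double alpha_max, double alpha_step) {
  const int N = A1.nrow(), L = A1.ncol();
  int maxA = 0;
  for (int l = 0; l < L; ++l) maxA = std::max(maxA, nAlleles[l]);

  // state
  std::vector<int> Z1(N * L, -1), Z2(N * L, -1);
  std::vector<double> P((size_t)K * L * maxA, 0.0);  // [k, l, a]
  NumericMatrix Q(N, K);
  double alpha = alpha_init;

  auto pidx = [&](int k, int l, int a) { return ((size_t)k * L + l) * maxA + a; };

  // init: random copy assignments, uniform Q
  for (int i = 0; i < N; ++i) {
    for (int l = 0; l < L; ++l) {
      if (A1(i, l) != NA_INTEGER) {
        Z1[(size_t)i * L + l] = (int)(R::unif_rand() * K);
        Z2[(size_t)i * L + l] = (int)(R::unif_rand() * K);
        if (Z1[(size_t)i * L + l] >= K) Z1[(size_t)i * L + l] = K - 1;
        if (Z2[(size_t)i * L + l] >= K) Z2[(size_t)i * L + l] = K - 1;
      }
    }
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;
  }

  NumericMatrix Qsum(N, K);
  std::vector<double> Psum((size_t)K * L * maxA, 0.0);
  NumericVector trace(nsweeps);
  std::vector<double> shape(maxA), draw(maxA), qshape(K), qdraw(K), prob(K);
  double sumlogQ = 0.0;

  const int total = burnin + nsweeps;
  for (int sweep = 0; sweep < total; ++sweep) {
    // ---- update P | Z (one counting pass over all allele copies)
    std::vector<double> cnt((size_t)K * L * maxA, 0.0);
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        const size_t zi = (size_t)i * L + l;
        if (Z1[zi] >= 0) {
          cnt[pidx(Z1[zi], l, A1(i, l) - 1)] += 1.0;
          cnt[pidx(Z2[zi], l, A2(i, l) - 1)] += 1.0;
        }
      }
    }
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        const int nA = nAlleles[l];
        double s = 0.0;
        for (int a = 0; a < nA; ++a) {
          double g = rgamma_pos(lambda + cnt[pidx(k, l, a)]);
          P[pidx(k, l, a)] = g;
          s += g;
        }
        for (int a = 0; a < nA; ++a) P[pidx(k, l, a)] /= s;
      }
    }
    // ---- update Q | Z
    sumlogQ = 0.0;
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < K; ++k) qshape[k] = alpha;
      for (int l = 0; l < L; ++l) {
        const size_t zi = (size_t)i * L + l;
        if (Z1[zi] >= 0) { qshape[Z1[zi]] += 1.0; qshape[Z2[zi]] += 1.0; }
      }
      dirichlet_draw(qshape, qdraw);
      for (int k = 0; k < K; ++k) Q(i, k) = qdraw[k];
      for (int k = 0; k < K; ++k) sumlogQ += std::log(std::max(qdraw[k], 1e-300));
    }
    // ---- update alpha by Metropolis (uniform prior on (0, alpha_max))
    if (K > 1) {
      double prop = alpha + R::norm_rand() * alpha_step;
      while (prop <= 0.0 || prop >= alpha_max) {
        if (prop <= 0.0) prop = -prop;
        if (prop >= alpha_max) prop = 2.0 * alpha_max - prop;
        if (prop == 0.0) break;
      }
      if (prop > 0.0 && prop < alpha_max) {
        double logr = N * (R::lgammafn(K * prop) - K * R::lgammafn(prop)
                         - R::lgammafn(K * alpha) + K * R::lgammafn(alpha))
                      + (prop - alpha) * sumlogQ;
        if (std::log(R::unif_rand()) < logr) alpha = prop;
      }
    }
    // ---- update Z | P, Q and data log-likelihood given assignments
    double loglik = 0.0;
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        const size_t zi = (size_t)i * L + l;
        if (A1(i, l) == NA_INTEGER) continue;
        for (int copy = 0; copy < 2; ++copy) {
          const int a = (copy == 0 ? A1(i, l) : A2(i, l)) - 1;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * P[pidx(k, l, a)];
            s += prob[k];
          }
          double u = R::unif_rand() * s, cum = 0.0;
          int znew = K - 1;
          for (int k = 0; k < K; ++k) { cum += prob[k]; if (u <= cum) { znew = k; break; } }
          if (copy == 0) Z1[zi] = znew; else Z2[zi] = znew;
          loglik += std::log(std::max(P[pidx(znew, l, a)], 1e-300));
        }
      }
    }
    // ---- accumulate after burn-in
    if (sweep >= burnin) {
      const int t = sweep - burnin;
      trace[t] = loglik;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (size_t m = 0; m < Psum.size(); ++m) Psum[m] += P[m];
    }
  }

  NumericMatrix Qmean(N, K);
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Qsum(i, k);
    for (int k = 0; k < K; ++k) Qmean(i, k) = (s > 0 ? Qsum(i, k) / s : 1.0 / K);
  }
  NumericVector Pmean((size_t)K * L * maxA);
  for (size_t m = 0; m < Psum.size(); ++m) Pmean[m] = Psum[m] / nsweeps;
  Pmean.attr("dim") = IntegerVector::create(maxA, L, K);  // filled [k,l,a] row-major -> reshape in R

  return List::create(_["Q"] = Qmean, _["P_raw"] = Pmean,
                      _["loglik_trace"] = trace, _["alpha"] = alpha);
}
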