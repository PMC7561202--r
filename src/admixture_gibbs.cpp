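#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler for the no-admixture-prior-free admixture model of
// multilocus co-dominant genotypes:
//   z_{ilc} | q_i        ~ Categorical(q_i)            (cluster of origin)
//   x_{ilc} | z=k        ~ Categorical(P_{kl.})        (allele copy)
//   P_{kl.}              ~ Dirichlet(lambda)           (independent freqs)
//   q_i                  ~ Dirichlet(alpha, ..., alpha)
//   alpha                ~ Uniform(0, alpha_max], Metropolis random walk
//
// geno: n x (2L) integer matrix of allele indices (1-based per locus),
//       0 = missing copy. Columns 2l-1, 2l are the two copies at locus l.
// Returns posterior-mean Q and P plus the thinned log-likelihood trace.

static double rdunif() { return unif_rand(); }

// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix geno, IntegerVector nAlleles, int K,
                         int burnin, int iters, int thin, double lambda,
                         double alpha_init, bool update_alpha,
                         double alpha_propsd, double alpha_max) {
  const int n = geno.nrow();
  const int L = nAlleles.size();
  if (geno.ncol() != 2 * L) stop("geno must have 2*L columns");
  if (K < 1) stop("K must be >= 1");
  if (iters < 1) stop("iters must be >= 1");
  if (thin < 1) thin = 1;

  std::vector<int> offset(L + 1, 0);
  for (int l = 0; l < L; ++l) offset[l + 1] = offset[l] + nAlleles[l];
  const int Jtot = offset[L];

  RNGScope scope;

  // state
  std::vector<double> P(K * Jtot);      // P[k*Jtot + offset[l] + a]
  std::vector<double> Q(n * K);         // Q[i*K + k]
  std::vector<int> z(n * 2 * L, -1);
  double alpha = alpha_init;

  // init: uniform
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l)
      for (int a = 0; a < nAlleles[l]; ++a)
        P[k * Jtot + offset[l] + a] = 1.0 / nAlleles[l];
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q[i * K + k] = 1.0 / K;

  std::vector<double> Qsum(n * K, 0.0), Psum(K * Jtot, 0.0);
  std::vector<double> cntP(K * Jtot);
  std::vector<double> cntQ(n * K);
  std::vector<double> prob(K);
  std::vector<double> lnl_trace;
  double sum_log_q = 0.0;  // sum_i sum_k log q_ik, for the alpha update
  int n_rec = 0;

  const int total = burnin + iters;
  for (int sweep = 0; sweep < total; ++sweep) {
    // --- sample z and accumulate counts ---
    std::fill(cntP.begin(), cntP.end(), 0.0);
    std::fill(cntQ.begin(), cntQ.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a == 0) continue;  // missing copy
          int col = offset[l] + a - 1;
          double s = 0.0;
          if (K == 1) {
            z[(i * L + l) * 2 + c] = 0;
            cntP[col] += 1.0;
            cntQ[i] += 1.0;
            continue;
          }
          for (int k = 0; k < K; ++k) {
            prob[k] = Q[i * K + k] * P[k * Jtot + col];
            s += prob[k];
          }
          double u = rdunif() * s;
          int k = 0;
          double acc = prob[0];
          while (u > acc && k < K - 1) { ++k; acc += prob[k]; }
          z[(i * L + l) * 2 + c] = k;
          cntP[k * Jtot + col] += 1.0;
          cntQ[i * K + k] += 1.0;
        }
      }
    }
    // --- update P ~ Dirichlet(lambda + counts) ---
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int a = 0; a < nAlleles[l]; ++a) {
          double g = R::rgamma(lambda + cntP[k * Jtot + offset[l] + a], 1.0);
          if (g < 1e-300) g = 1e-300;
          P[k * Jtot + offset[l] + a] = g;
          s += g;
        }
        for (int a = 0; a < nAlleles[l]; ++a)
          P[k * Jtot + offset[l] + a] /= s;
      }
    }
    // --- update Q ~ Dirichlet(alpha + copy counts) ---
    sum_log_q = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + cntQ[i * K + k], 1.0);
        if (g < 1e-300) g = 1e-300;
        Q[i * K + k] = g;
        s += g;
      }
      for (int k = 0; k < K; ++k) {
        Q[i * K + k] /= s;
        if (Q[i * K + k] < 1e-12) Q[i * K + k] = 1e-12;
        sum_log_q += std::log(Q[i * K + k]);
      }
    }
    // --- Metropolis update of alpha (uniform prior on (0, alpha_max]) ---
    if (update_alpha && K > 1) {
      double alpha_new = alpha + norm_rand() * alpha_propsd;
      if (alpha_new > 0 && alpha_new <= alpha_max) {
        double lp_new = n * (R::lgammafn(K * alpha_new) -
                             K * R::lgammafn(alpha_new)) +
                        (alpha_new - 1.0) * sum_log_q;
        double lp_old = n * (R::lgammafn(K * alpha) -
                             K * R::lgammafn(alpha)) +
                        (alpha - 1.0) * sum_log_q;
        if (std::log(rdunif()) < lp_new - lp_old) alpha = alpha_new;
      }
    }
    // --- record ---
    if (sweep >= burnin) {
      for (int i = 0; i < n * K; ++i) Qsum[i] += Q[i];
      for (int i = 0; i < K * Jtot; ++i) Psum[i] += P[i];
      ++n_rec;
      if ((sweep - burnin) % thin == 0) {
        double lnl = 0.0;
        for (int i = 0; i < n; ++i)
          for (int l = 0; l < L; ++l)
            for (int c = 0; c < 2; ++c) {
              int a = geno(i, 2 * l + c);
              if (a == 0) continue;
              int col = offset[l] + a - 1;
              double s = 0.0;
              for (int k = 0; k < K; ++k)
                s += Q[i * K + k] * P[k * Jtot + col];
              lnl += std::log(s > 1e-300 ? s : 1e-300);
            }
        lnl_trace.push_back(lnl);
      }
    }
  }

  NumericMatrix Qout(n, K), Pout(K, Jtot);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Qsum[i * K + k];
    for (int k = 0; k < K; ++k) Qout(i, k) = Qsum[i * K + k] / s;
  }
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < Jtot; ++j) Pout(k, j) = Psum[k * Jtot + j] / n_rec;
  }
  return List::create(_["Q"] = Qout, _["P"] = Pout,
                      _["lnL_trace"] = NumericVector(lnl_trace.begin(),
                                                     lnl_trace.end()),
                      _["alpha"] = alpha);
}
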