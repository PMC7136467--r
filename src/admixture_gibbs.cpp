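#include <Rcpp.h>
using namespace Rcpp;

// Balding-Nichols log-density of p under Beta(pb*(1-F)/F, (1-pb)*(1-F)/F)
static inline double bn_logdens(double p, double pb, double F) {
  double c = (1.0 - F) / F;
  double a = pb * c, b = (1.0 - pb) * c;
  return R::lgammafn(a + b) - R::lgammafn(a) - R::lgammafn(b) +
         (a - 1.0) * std::log(p) + (b - 1.0) * std::log(1.0 - p);
}

static inline double clamp01(double x) {
  const double eps = 1e-9;
  if (x < eps) return eps;
  if (x > 1.0 - eps) return 1.0 - eps;
  return x;
}

// Gibbs sampler for the admixture model with correlated allele frequencies.
// G: n x L genotype matrix of A1-allele counts, -1 = missing.
// Returns posterior means over post-burn-in sweeps and the per-sweep
// data log-likelihood trace.
// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix G, int K, int burnin, int reps,
                         double alpha_init, double lambda,
                         double alpha_max, double alpha_step,
                         double f_step, double pbar_step) {
  const int n = G.nrow(), L = G.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > n) stop("K exceeds the number of individuals");

  NumericMatrix Q(n, K), P(K, L);
  NumericVector pbar(L), Fk(K);
  double alpha = alpha_init;

  // initialization from the priors
  for (int l = 0; l < L; ++l) pbar[l] = clamp01(R::rbeta(lambda, lambda));
  for (int k = 0; k < K; ++k) Fk[k] = 0.05 + 0.1 * R::unif_rand();
  for (int k = 0; k < K; ++k) {
    double c = (1.0 - Fk[k]) / Fk[k];
    for (int l = 0; l < L; ++l)
      P(k, l) = clamp01(R::rbeta(pbar[l] * c, (1.0 - pbar[l]) * c));
  }
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { Q(i, k) = R::rgamma(alpha, 1.0); s += Q(i, k); }
    for (int k = 0; k < K; ++k) Q(i, k) /= s;
  }

  NumericMatrix Qsum(n, K), Psum(K, L);
  NumericVector Fsum(K);
  double alpha_sum = 0.0;
  NumericVector lnl_trace(burnin + reps);

  std::vector<double> prob(K), nk(n * K), x1(K * L), x0(K * L);
  const int total = burnin + reps;

  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(nk.begin(), nk.end(), 0.0);
    std::fill(x1.begin(), x1.end(), 0.0);
    std::fill(x0.begin(), x0.end(), 0.0);

    // -- z: ancestry of each allele copy, given (Q, P)
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int g = G(i, l);
        if (g < 0) continue;        // missing copies carry no likelihood
        for (int copy = 0; copy < 2; ++copy) {
          int a = (copy == 0) ? (g >= 1 ? 1 : 0) : (g == 2 ? 1 : 0);
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            double lik = a ? P(k, l) : 1.0 - P(k, l);
            prob[k] = Q(i, k) * lik;
            s += prob[k];
          }
          double u = R::unif_rand() * s, acc = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += prob[k];
            if (u <= acc) { z = k; break; }
          }
          nk[i * K + z] += 1.0;
          if (a) x1[z * L + l] += 1.0; else x0[z * L + l] += 1.0;
        }
      }
    }

    // -- Q | z: Dirichlet(alpha + counts)
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        Q(i, k) = R::rgamma(alpha + nk[i * K + k], 1.0);
        if (Q(i, k) < 1e-300) Q(i, k) = 1e-300;
        s += Q(i, k);
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= s;
    }

    // -- P | z: Beta(BN prior + allele counts)
    for (int k = 0; k < K; ++k) {
      double c = (1.0 - Fk[k]) / Fk[k];
      for (int l = 0; l < L; ++l)
        P(k, l) = clamp01(R::rbeta(pbar[l] * c + x1[k * L + l],
                                   (1.0 - pbar[l]) * c + x0[k * L + l]));
    }

    // -- ancestral frequencies: random-walk Metropolis per locus
    for (int l = 0; l < L; ++l) {
      double cur = pbar[l];
      double prop = cur + pbar_step * R::norm_rand();
      if (prop <= 0.0 || prop >= 1.0) continue;
      double lr = (lambda - 1.0) *
        (std::log(prop) + std::log(1.0 - prop) -
         std::log(cur) - std::log(1.0 - cur));
      for (int k = 0; k < K; ++k)
        lr += bn_logdens(P(k, l), prop, Fk[k]) -
              bn_logdens(P(k, l), cur, Fk[k]);
      if (std::log(R::unif_rand()) < lr) pbar[l] = prop;
    }

    // -- drift F_k: random-walk Metropolis, uniform(0,1) prior
    for (int k = 0; k < K; ++k) {
      double cur = Fk[k];
      double prop = cur + f_step * R::norm_rand();
      if (prop <= 1e-4 || prop >= 1.0 - 1e-4) continue;
      double lr = 0.0;
      for (int l = 0; l < L; ++l)
        lr += bn_logdens(P(k, l), pbar[l], prop) -
              bn_logdens(P(k, l), pbar[l], cur);
      if (std::log(R::unif_rand()) < lr) Fk[k] = prop;
    }

    // -- alpha: random-walk Metropolis, uniform(0, alpha_max] prior
    if (K > 1) {
      double prop = alpha + alpha_step * R::norm_rand();
      if (prop > 1e-4 && prop <= alpha_max) {
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) slq += std::log(Q(i, k));
        double lr = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop) -
                         R::lgammafn(K * alpha) + K * R::lgammafn(alpha)) +
                    (prop - alpha) * slq;
        if (std::log(R::unif_rand()) < lr) alpha = prop;
      }
    }

    // -- data log-likelihood under current (Q, P)
    double lnl = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int g = G(i, l);
        if (g < 0) continue;
        double m = 0.0;
        for (int k = 0; k < K; ++k) m += Q(i, k) * P(k, l);
        m = clamp01(m);
        if (g == 0) lnl += 2.0 * std::log(1.0 - m);
        else if (g == 2) lnl += 2.0 * std::log(m);
        else lnl += std::log(2.0) + std::log(m) + std::log(1.0 - m);
      }
    }
    if (!std::isfinite(lnl))
      stop("chain numerical underflow at sweep %d", sweep + 1);
    lnl_trace[sweep] = lnl;

    if (sweep >= burnin) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) Psum(k, l) += P(k, l);
      for (int k = 0; k < K; ++k) Fsum[k] += Fk[k];
      alpha_sum += alpha;
    }
  }

  const double m = reps;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= m;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) Psum(k, l) /= m;
  for (int k = 0; k < K; ++k) Fsum[k] /= m;

  return List::create(_["Q"] = Qsum, _["P"] = Psum, _["F_k"] = Fsum,
                      _["alpha"] = alpha_sum / m,
                      _["lnl_trace"] = lnl_trace);
}
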