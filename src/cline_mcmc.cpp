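// Metropolis-within-Gibbs sampler for the Bayesian genomic cline model.
//
// State: per-admixed-individual hybrid indices h_i (Uniform(0,1) prior),
// per-locus cline parameters alpha_j, beta_j (independent zero-mean normal
// priors), and parental allele frequencies p0_j, p1_j (Beta(1,1) priors,
// Gibbs-resampled each sweep from the parental allele counts unless fixed).
// The ancestry probability of a gene copy is
//   phi = h + 2 h (1 - h) (alpha + beta (2 h - 1)),
// truncated into [trunc, 1 - trunc], and a genotype is Binomial(2, q) with
// q = phi * p1 + (1 - phi) * p0. In read-count mode the genotype is latent and
// the likelihood sums over g in {0,1,2} with a binomial read layer whose
// per-read alt probability is (g/2)(1-e) + (1-g/2)e; that layer depends only
// on the data and is precomputed.
//
// Random-walk proposal scales adapt toward ~35% acceptance during burn-in
// only. All randomness comes from R's RNG, so a chain is reproducible from
// the R-side seed.

#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double phi_fun(double h, double a, double b, double trunc) {
  double phi = h + 2.0 * h * (1.0 - h) * (a + b * (2.0 * h - 1.0));
  return clamp(phi, trunc, 1.0 - trunc);
}

namespace {

struct ClineData {
  int L, N, mode;                 // loci, admixed individuals, 0=known 1=reads
  const int *G;                   // L x N genotypes, -1 missing (known mode)
  std::vector<double> B0, B1, B2; // L x N scaled read likelihoods (reads mode)

  double loglik(int j, int i, double q) const {
    q = clamp(q, 1e-12, 1.0 - 1e-12);
    if (mode == 0) {
      int g = G[j + (size_t)i * L];
      if (g < 0) return 0.0;
      if (g == 0) return 2.0 * log1p(-q);
      if (g == 1) return M_LN2 + log(q) + log1p(-q);
      return 2.0 * log(q);
    }
    size_t k = j + (size_t)i * L;
    double om = 1.0 - q;
    double lik = B0[k] * om * om + B1[k] * 2.0 * q * om + B2[k] * q * q;
    return log(lik > 0 ? lik : 1e-300);
  }
};

} // namespace

// [[Rcpp::export(name = ".cline_chain_cpp")]]
List cline_chain_cpp(IntegerMatrix G, NumericMatrix DP, NumericMatrix ALT,
                     int mode, double seq_error,
                     NumericVector alt0, NumericVector n0,
                     NumericVector alt1, NumericVector n1,
                     bool fix_parental,
                     NumericVector p0_fix, NumericVector p1_fix,
                     int n_steps, int burn_in, int thin,
                     double prior_sd_alpha, double prior_sd_beta,
                     double trunc, NumericVector h_init) {
  const int L = G.nrow(), N = G.ncol();
  ClineData dat;
  dat.L = L; dat.N = N; dat.mode = mode; dat.G = G.begin();

  if (mode == 1) {
    // precompute read-layer likelihoods P(reads | g), rescaled per cell so the
    // largest of the three is 1 (the constant cancels in Metropolis ratios)
    dat.B0.resize((size_t)L * N); dat.B1.resize((size_t)L * N); dat.B2.resize((size_t)L * N);
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < L; ++j) {
        size_t k = j + (size_t)i * L;
        double dp = DP(j, i), alt = ALT(j, i);
        if (!R_finite(dp) || dp <= 0) { dat.B0[k] = dat.B1[k] = dat.B2[k] = 1.0; continue; }
        double e0 = seq_error, e1 = 0.5, e2 = 1.0 - seq_error;
        double b0 = R::dbinom(alt, dp, e0, 1);
        double b1 = R::dbinom(alt, dp, e1, 1);
        double b2 = R::dbinom(alt, dp, e2, 1);
        double m = std::max(b0, std::max(b1, b2));
        dat.B0[k] = exp(b0 - m); dat.B1[k] = exp(b1 - m); dat.B2[k] = exp(b2 - m);
      }
    }
  }

  std::vector<double> h(h_init.begin(), h_init.end());
  std::vector<double> alpha(L, 0.0), beta(L, 0.0), p0(L), p1(L);
  for (int j = 0; j < L; ++j) {
    p0[j] = fix_parental ? p0_fix[j] : (alt0[j] + 1.0) / (n0[j] + 2.0);
    p1[j] = fix_parental ? p1_fix[j] : (alt1[j] + 1.0) / (n1[j] + 2.0);
  }

  std::vector<double> LL((size_t)L * N), rowSum(L), colSum(N);
  std::vector<double> qcol(L), newcol(L), newrow(N);
  auto refresh_ll = [&]() {
    std::fill(rowSum.begin(), rowSum.end(), 0.0);
    std::fill(colSum.begin(), colSum.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < L; ++j) {
        double phi = phi_fun(h[i], alpha[j], beta[j], trunc);
        double ll = dat.loglik(j, i, phi * p1[j] + (1.0 - phi) * p0[j]);
        LL[j + (size_t)i * L] = ll;
        rowSum[j] += ll; colSum[i] += ll;
      }
    }
  };

  // adaptive proposal scales
  std::vector<double> s_h(N, 0.1), s_a(L, 0.5), s_b(L, 0.5);
  std::vector<int> acc_h(N, 0), acc_a(L, 0), acc_b(L, 0);
  const int adapt_window = 50;
  auto adapt = [](std::vector<double> &s, std::vector<int> &acc, int win) {
    for (size_t k = 0; k < s.size(); ++k) {
      double rate = (double)acc[k] / win;
      s[k] = clamp(s[k] * exp(1.2 * (rate - 0.35)), 1e-4, 10.0);
      acc[k] = 0;
    }
  };

  const int n_save = (n_steps - burn_in) / thin;
  NumericMatrix out_alpha(n_save, L), out_beta(n_save, L), out_h(n_save, N);
  const double va = prior_sd_alpha * prior_sd_alpha;
  const double vb = prior_sd_beta * prior_sd_beta;

  RNGScope scope;
  refresh_ll();
  int saved = 0;

  for (int it = 1; it <= n_steps; ++it) {
    // -- Gibbs refresh of parental allele frequencies -----------------------
    if (!fix_parental) {
      for (int j = 0; j < L; ++j) {
        p0[j] = R::rbeta(alt0[j] + 1.0, n0[j] - alt0[j] + 1.0);
        p1[j] = R::rbeta(alt1[j] + 1.0, n1[j] - alt1[j] + 1.0);
      }
      refresh_ll();
    }

    // -- hybrid indices -----------------------------------------------------
    for (int i = 0; i < N; ++i) {
      double hp = h[i] + R::norm_rand() * s_h[i];
      if (hp < 0.0 || hp > 1.0) continue; // zero prior mass outside [0,1]
      double newsum = 0.0;
      for (int j = 0; j < L; ++j) {
        double phi = phi_fun(hp, alpha[j], beta[j], trunc);
        newcol[j] = dat.loglik(j, i, phi * p1[j] + (1.0 - phi) * p0[j]);
        newsum += newcol[j];
      }
      if (log(R::unif_rand()) < newsum - colSum[i]) {
        for (int j = 0; j < L; ++j) {
          rowSum[j] += newcol[j] - LL[j + (size_t)i * L];
          LL[j + (size_t)i * L] = newcol[j];
        }
        colSum[i] = newsum;
        h[i] = hp;
        ++acc_h[i];
      }
    }

    // -- cline parameters ---------------------------------------------------
    for (int rep = 0; rep < 2; ++rep) { // rep 0: alpha, rep 1: beta
      std::vector<double> &par = rep == 0 ? alpha : beta;
      std::vector<double> &s = rep == 0 ? s_a : s_b;
      std::vector<int> &acc = rep == 0 ? acc_a : acc_b;
      const double pv = rep == 0 ? va : vb;
      for (int j = 0; j < L; ++j) {
        double prop = par[j] + R::norm_rand() * s[j];
        double a = rep == 0 ? prop : alpha[j];
        double b = rep == 0 ? beta[j] : prop;
        double newsum = 0.0;
        for (int i = 0; i < N; ++i) {
          double phi = phi_fun(h[i], a, b, trunc);
          newrow[i] = dat.loglik(j, i, phi * p1[j] + (1.0 - phi) * p0[j]);
          newsum += newrow[i];
        }
        double dprior = (par[j] * par[j] - prop * prop) / (2.0 * pv);
        if (log(R::unif_rand()) < newsum - rowSum[j] + dprior) {
          for (int i = 0; i < N; ++i) {
            colSum[i] += newrow[i] - LL[j + (size_t)i * L];
            LL[j + (size_t)i * L] = newrow[i];
          }
          rowSum[j] = newsum;
          par[j] = prop;
          ++acc[j];
        }
      }
    }

    if (it <= burn_in && it % adapt_window == 0) {
      adapt(s_h, acc_h, adapt_window);
      adapt(s_a, acc_a, adapt_window);
      adapt(s_b, acc_b, adapt_window);
    } else if (it == burn_in) {
      std::fill(acc_h.begin(), acc_h.end(), 0);
      std::fill(acc_a.begin(), acc_a.end(), 0);
      std::fill(acc_b.begin(), acc_b.end(), 0);
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < L; ++j) { out_alpha(saved, j) = alpha[j]; out_beta(saved, j) = beta[j]; }
      for (int i = 0; i < N; ++i) out_h(saved, i) = h[i];
      ++saved;
    }
  }

  return List::create(_["alpha"] = out_alpha, _["beta"] = out_beta, _["h"] = out_h);
}

// Reference-path likelihood for one (genotype | phi, p0, p1) observation;
// exported for cross-checking the R implementation against the sampler's.
// [[Rcpp::export(name = ".cline_loglik_cpp")]]
double cline_loglik_cpp(int g, double dp, double alt, int mode, double seq_error,
                        double h, double a, double b, double trunc,
                        double p0, double p1) {
  ClineData dat;
  int gg = g;
  dat.L = 1; dat.N = 1; dat.mode = mode; dat.G = &gg;
  if (mode == 1) {
    dat.B0.resize(1); dat.B1.resize(1); dat.B2.resize(1);
    if (dp > 0) {
      // unscaled here (unlike the sampler) so the value is an absolute
      // log-likelihood comparable with the R reference implementation
      dat.B0[0] = R::dbinom(alt, dp, seq_error, 0);
      dat.B1[0] = R::dbinom(alt, dp, 0.5, 0);
      dat.B2[0] = R::dbinom(alt, dp, 1.0 - seq_error, 0);
    } else {
      dat.B0[0] = dat.B1[0] = dat.B2[0] = 1.0;
    }
  }
  double phi = phi_fun(h, a, b, trunc);
  return dat.loglik(0, 0, phi * p1 + (1.0 - phi) * p0);
}
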