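#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the three-level normal hierarchy
//   y_i      ~ N(theta_s[i], sig_e^2)          (observations within species)
//   theta_s  ~ N(phi_p[s],   sig_s^2)          (species within phyla)
//   phi_p    ~ N(mu,         sig_p^2)          (phyla around the location)
//   mu       ~ N(m0, v0^2)
// with independent half-Cauchy(0, A_k) priors on the three SDs. Location
// parameters are conditionally conjugate; the SDs are updated by slice
// sampling on log(sigma). All randomness comes from R's RNG, so results are
// reproducible under set.seed().

// conditional log-density of x = log(sigma) given `cnt` deviations with sum
// of squares `ss`: -(cnt-1)x - ss/(2 e^{2x}) + log half-Cauchy, Jacobian
// included in the -(cnt-1) term.
static inline double logpost_logsd(double x, double ss, double cnt, double A) {
  double s2 = std::exp(2.0 * x);
  return -(cnt - 1.0) * x - ss / (2.0 * s2) - std::log1p(s2 / (A * A));
}

// univariate slice sampler (stepping out + shrinkage; Neal 2003) on
// log(sigma), bounded to [lo, hi] to keep degenerate conditionals (ss == 0)
// proper.
static double slice_logsd(double x0, double ss, double cnt, double A,
                          double lo, double hi, double w, int mmax) {
  if (x0 < lo) x0 = lo;
  if (x0 > hi) x0 = hi;
  double logy = logpost_logsd(x0, ss, cnt, A) + std::log(unif_rand());
  double u = w * unif_rand();
  double L = x0 - u;
  double R = x0 + (w - u);
  int j = (int)std::floor(mmax * unif_rand());
  int k = mmax - 1 - j;
  while (j-- > 0 && L > lo && logpost_logsd(L, ss, cnt, A) > logy) L -= w;
  while (k-- > 0 && R < hi && logpost_logsd(R, ss, cnt, A) > logy) R += w;
  if (L < lo) L = lo;
  if (R > hi) R = hi;
  for (int it = 0; it < 1000; ++it) {
    double x1 = L + (R - L) * unif_rand();
    if (logpost_logsd(x1, ss, cnt, A) >= logy) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

// [[Rcpp::export]]
List gibbs_hierarchy_cpp(NumericVector y, IntegerVector species_of_obs,
                         IntegerVector phylum_of_species, int n_phyla,
                         int n_iter, int burn, int thin,
                         double m0, double v0, NumericVector prior_scale,
                         NumericVector init_theta, NumericVector init_phi,
                         double init_mu, NumericVector init_sigma,
                         LogicalVector fix_sigma, NumericVector fixed_sigma,
                         bool fix_mu, double fixed_mu,
                         double sigma_floor, bool save_species) {
  const int n = y.size();
  const int S = init_theta.size();
  const int P = n_phyla;

  // per-species sufficient statistics
  std::vector<double> sum_y(S, 0.0);
  std::vector<int> n_s(S, 0);
  for (int i = 0; i < n; ++i) {
    int s = species_of_obs[i];
    sum_y[s] += y[i];
    n_s[s] += 1;
  }
  std::vector<int> J_p(P, 0);
  for (int s = 0; s < S; ++s) J_p[phylum_of_species[s]] += 1;

  std::vector<double> theta(init_theta.begin(), init_theta.end());
  std::vector<double> phi(init_phi.begin(), init_phi.end());
  double mu = fix_mu ? fixed_mu : init_mu;
  double sig[3];  // 0 = phylum, 1 = species, 2 = residual
  for (int k = 0; k < 3; ++k)
    sig[k] = fix_sigma[k] ? fixed_sigma[k] : std::max(init_sigma[k], sigma_floor);

  const double lo = std::log(sigma_floor);
  int n_keep = 0;
  for (int it = burn; it < n_iter; ++it) if ((it - burn) % thin == 0) ++n_keep;

  NumericVector keep_mu(n_keep);
  NumericMatrix keep_phi(n_keep, P);
  NumericMatrix keep_sigma(n_keep, 3);
  NumericMatrix keep_theta(save_species ? n_keep : 0, save_species ? S : 0);

  RNGScope scope;
  int kidx = 0;
  for (int it = 0; it < n_iter; ++it) {
    double sigp2 = sig[0] * sig[0];
    double sigs2 = sig[1] * sig[1];
    double sige2 = sig[2] * sig[2];

    // species means
    for (int s = 0; s < S; ++s) {
      double prec = n_s[s] / sige2 + 1.0 / sigs2;
      double mean = (sum_y[s] / sige2 + phi[phylum_of_species[s]] / sigs2) / prec;
      theta[s] = mean + norm_rand() / std::sqrt(prec);
    }
    // phylum means
    std::vector<double> sum_theta(P, 0.0);
    for (int s = 0; s < S; ++s) sum_theta[phylum_of_species[s]] += theta[s];
    for (int p = 0; p < P; ++p) {
      double prec = J_p[p] / sigs2 + 1.0 / sigp2;
      double mean = (sum_theta[p] / sigs2 + mu / sigp2) / prec;
      phi[p] = mean + norm_rand() / std::sqrt(prec);
    }
    // top-level location
    if (!fix_mu) {
      double sum_phi = 0.0;
      for (int p = 0; p < P; ++p) sum_phi += phi[p];
      double prec = P / sigp2 + 1.0 / (v0 * v0);
      double mean = (sum_phi / sigp2 + m0 / (v0 * v0)) / prec;
      mu = mean + norm_rand() / std::sqrt(prec);
    }
    // scale parameters
    if (!fix_sigma[2]) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = y[i] - theta[species_of_obs[i]];
        ss += d * d;
      }
      double hi = std::log(prior_scale[2]) + 14.0;
      sig[2] = std::exp(slice_logsd(std::log(sig[2]), ss, (double)n,
                                    prior_scale[2], lo, hi, 1.0, 50));
    }
    if (!fix_sigma[1]) {
      double ss = 0.0;
      for (int s = 0; s < S; ++s) {
        double d = theta[s] - phi[phylum_of_species[s]];
        ss += d * d;
      }
      double hi = std::log(prior_scale[1]) + 14.0;
      sig[1] = std::exp(slice_logsd(std::log(sig[1]), ss, (double)S,
                                    prior_scale[1], lo, hi, 1.0, 50));
    }
    if (!fix_sigma[0]) {
      double ss = 0.0;
      for (int p = 0; p < P; ++p) {
        double d = phi[p] - mu;
        ss += d * d;
      }
      double hi = std::log(prior_scale[0]) + 14.0;
      sig[0] = std::exp(slice_logsd(std::log(sig[0]), ss, (double)P,
                                    prior_scale[0], lo, hi, 1.0, 50));
    }

    if (it >= burn && (it - burn) % thin == 0) {
      keep_mu[kidx] = mu;
      for (int p = 0; p < P; ++p) keep_phi(kidx, p) = phi[p];
      for (int k = 0; k < 3; ++k) keep_sigma(kidx, k) = sig[k];
      if (save_species)
        for (int s = 0; s < S; ++s) keep_theta(kidx, s) = theta[s];
      ++kidx;
    }
  }

  return List::create(_["mu"] = keep_mu, _["phi"] = keep_phi,
                      _["sigma"] = keep_sigma, _["theta"] = keep_theta);
}
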