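#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the binomial APC model with RW1
// smoothing priors:
//   y_ap ~ Binomial(n_ap, plogis(mu + alpha_a + beta_p + gamma_c)),
//   first differences of each effect ~ N(0, 1/tau_scale),
//   tau_scale ~ Gamma(shape, rate),  mu ~ N(mu_mean, mu_var).
// Single-site Gaussian random-walk updates for mu/alpha/beta/gamma with
// step sizes adapted during burn-in; conjugate Gamma updates for the
// precisions. After each sweep the effects are recentred by the
// likelihood-invariant transformation that keeps all curves sum-to-zero
// and the period curve detrended (drift assigned to the cohort scale).
// Uses R's RNG, so runs are reproducible under set.seed() in R.

static inline double cell_ll(double y, double n, double eta) {
  if (eta > 0) return y * eta - n * (eta + log1p(exp(-eta)));
  return y * eta - n * log1p(exp(eta));
}

// change in the RW1 log prior when x[i] -> newv
static inline double rw1_delta(const std::vector<double>& x, int i,
                               double newv, double tau) {
  double d = 0.0;
  int m = (int)x.size();
  if (i > 0) {
    double o = x[i] - x[i - 1], nn = newv - x[i - 1];
    d += -0.5 * tau * (nn * nn - o * o);
  }
  if (i < m - 1) {
    double o = x[i + 1] - x[i], nn = x[i + 1] - newv;
    d += -0.5 * tau * (nn * nn - o * o);
  }
  return d;
}

static inline double sum_sq_diff(const std::vector<double>& x) {
  double ss = 0.0;
  for (size_t i = 1; i < x.size(); ++i) {
    double d = x[i] - x[i - 1];
    ss += d * d;
  }
  return ss;
}

// [[Rcpp::export]]
List apc_gibbs_cpp(NumericMatrix y, NumericMatrix n,
                   double mu_init, NumericVector alpha_init,
                   NumericVector beta_init, NumericVector gamma_init,
                   NumericVector tau_init,
                   NumericVector prior_shape, NumericVector prior_rate,
                   double mu_mean, double mu_var,
                   int iterations, int burn_in, int thin,
                   bool update_effects, bool recentre) {
  const int A = y.nrow(), P = y.ncol(), C = A + P - 1;
  if (alpha_init.size() != A || beta_init.size() != P || gamma_init.size() != C)
    stop("effect initial values have inconsistent lengths");
  if (iterations <= burn_in || thin < 1) stop("bad MCMC configuration");

  std::vector<double> alpha(alpha_init.begin(), alpha_init.end());
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> gamma(gamma_init.begin(), gamma_init.end());
  double mu = mu_init;
  double tau_a = tau_init[0], tau_b = tau_init[1], tau_c = tau_init[2];

  // cells of each cohort diagonal (0-based c = p - a + A - 1)
  std::vector<std::vector<std::pair<int, int> > > ccell(C);
  for (int a = 0; a < A; ++a)
    for (int p = 0; p < P; ++p)
      ccell[p - a + A - 1].push_back(std::make_pair(a, p));

  NumericMatrix eta(A, P);
  auto refresh_eta = [&]() {
    for (int a = 0; a < A; ++a)
      for (int p = 0; p < P; ++p)
        eta(a, p) = mu + alpha[a] + beta[p] + gamma[p - a + A - 1];
  };
  refresh_eta();

  // adaptive step sizes and acceptance bookkeeping
  std::vector<double> sa(A, 0.05), sb(P, 0.05), sg(C, 0.05);
  double sm = 0.02;
  std::vector<int> acc_a(A, 0), acc_b(P, 0), acc_g(C, 0);
  int acc_m = 0, att = 0;
  const double target = 0.44;

  const int S = (iterations - burn_in) / thin;
  NumericVector out_mu(S);
  NumericMatrix out_alpha(S, A), out_beta(S, P), out_gamma(S, C), out_tau(S, 3);
  int s_out = 0;

  RNGScope scope;

  for (int it = 1; it <= iterations; ++it) {
    if (update_effects) {
      // --- age effects (row a of the grid) ---
      for (int a = 0; a < A; ++a) {
        double prop = alpha[a] + R::norm_rand() * sa[a];
        double d = rw1_delta(alpha, a, prop, tau_a);
        double shift = prop - alpha[a];
        for (int p = 0; p < P; ++p)
          d += cell_ll(y(a, p), n(a, p), eta(a, p) + shift)
             - cell_ll(y(a, p), n(a, p), eta(a, p));
        if (log(R::unif_rand()) < d) {
          alpha[a] = prop;
          for (int p = 0; p < P; ++p) eta(a, p) += shift;
          ++acc_a[a];
        }
      }
      // --- period effects (column p) ---
      for (int p = 0; p < P; ++p) {
        double prop = beta[p] + R::norm_rand() * sb[p];
        double d = rw1_delta(beta, p, prop, tau_b);
        double shift = prop - beta[p];
        for (int a = 0; a < A; ++a)
          d += cell_ll(y(a, p), n(a, p), eta(a, p) + shift)
             - cell_ll(y(a, p), n(a, p), eta(a, p));
        if (log(R::unif_rand()) < d) {
          beta[p] = prop;
          for (int a = 0; a < A; ++a) eta(a, p) += shift;
          ++acc_b[p];
        }
      }
      // --- cohort effects (diagonal c) ---
      for (int c = 0; c < C; ++c) {
        double prop = gamma[c] + R::norm_rand() * sg[c];
        double d = rw1_delta(gamma, c, prop, tau_c);
        double shift = prop - gamma[c];
        for (size_t k = 0; k < ccell[c].size(); ++k) {
          int a = ccell[c][k].first, p = ccell[c][k].second;
          d += cell_ll(y(a, p), n(a, p), eta(a, p) + shift)
             - cell_ll(y(a, p), n(a, p), eta(a, p));
        }
        if (log(R::unif_rand()) < d) {
          gamma[c] = prop;
          for (size_t k = 0; k < ccell[c].size(); ++k)
            eta(ccell[c][k].first, ccell[c][k].second) += shift;
          ++acc_g[c];
        }
      }
      // --- intercept ---
      {
        double prop = mu + R::norm_rand() * sm;
        double d = -0.5 * ((prop - mu_mean) * (prop - mu_mean)
                         - (mu - mu_mean) * (mu - mu_mean)) / mu_var;
        double shift = prop - mu;
        for (int a = 0; a < A; ++a)
          for (int p = 0; p < P; ++p)
            d += cell_ll(y(a, p), n(a, p), eta(a, p) + shift)
               - cell_ll(y(a, p), n(a, p), eta(a, p));
        if (log(R::unif_rand()) < d) {
          mu = prop;
          ++acc_m;
          refresh_eta();
        }
      }
    }

    // --- conjugate precision updates ---
    tau_a = R::rgamma(prior_shape[0] + 0.5 * (A - 1),
                      1.0 / (prior_rate[0] + 0.5 * sum_sq_diff(alpha)));
    tau_b = R::rgamma(prior_shape[1] + 0.5 * (P - 1),
                      1.0 / (prior_rate[1] + 0.5 * sum_sq_diff(beta)));
    tau_c = R::rgamma(prior_shape[2] + 0.5 * (C - 1),
                      1.0 / (prior_rate[2] + 0.5 * sum_sq_diff(gamma)));

    // --- recentre: likelihood-invariant identifiability transformation ---
    if (update_effects && recentre) {
      double pbar = 0.5 * (P + 1), num = 0.0, den = 0.0;
      double bbar = 0.0;
      for (int p = 0; p < P; ++p) bbar += beta[p];
      bbar /= P;
      for (int p = 0; p < P; ++p) {
        num += (p + 1 - pbar) * (beta[p] - bbar);
        den += (p + 1 - pbar) * (p + 1 - pbar);
      }
      double slope = (P > 1) ? num / den : 0.0;
      for (int p = 0; p < P; ++p) beta[p] -= slope * (p + 1);
      for (int a = 0; a < A; ++a) alpha[a] += slope * (a + 1);
      for (int c = 0; c < C; ++c) gamma[c] += slope * (c + 1);
      mu -= slope * A;
      double ma = 0, mb = 0, mc = 0;
      for (int a = 0; a < A; ++a) ma += alpha[a];
      for (int p = 0; p < P; ++p) mb += beta[p];
      for (int c = 0; c < C; ++c) mc += gamma[c];
      ma /= A; mb /= P; mc /= C;
      for (int a = 0; a < A; ++a) alpha[a] -= ma;
      for (int p = 0; p < P; ++p) beta[p] -= mb;
      for (int c = 0; c < C; ++c) gamma[c] -= mc;
      mu += ma + mb + mc;
      refresh_eta();
    }

    ++att;
    // --- step-size adaptation during burn-in ---
    if (update_effects && it <= burn_in && it % 100 == 0) {
      auto adapt = [&](std::vector<double>& s, std::vector<int>& acc) {
        for (size_t i = 0; i < s.size(); ++i) {
          double r = (double)acc[i] / att;
          double f = exp(r - target);
          if (f < 0.5) f = 0.5;
          if (f > 2.0) f = 2.0;
          s[i] *= f;
          acc[i] = 0;
        }
      };
      adapt(sa, acc_a);
      adapt(sb, acc_b);
      adapt(sg, acc_g);
      double r = (double)acc_m / att;
      double f = exp(r - target);
      if (f < 0.5) f = 0.5;
      if (f > 2.0) f = 2.0;
      sm *= f;
      acc_m = 0;
      att = 0;
    }
    if (it == burn_in) {  // freeze steps; count acceptance on the kept part
      std::fill(acc_a.begin(), acc_a.end(), 0);
      std::fill(acc_b.begin(), acc_b.end(), 0);
      std::fill(acc_g.begin(), acc_g.end(), 0);
      acc_m = 0;
      att = 0;
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && s_out < S) {
      out_mu[s_out] = mu;
      for (int a = 0; a < A; ++a) out_alpha(s_out, a) = alpha[a];
      for (int p = 0; p < P; ++p) out_beta(s_out, p) = beta[p];
      for (int c = 0; c < C; ++c) out_gamma(s_out, c) = gamma[c];
      out_tau(s_out, 0) = tau_a;
      out_tau(s_out, 1) = tau_b;
      out_tau(s_out, 2) = tau_c;
      ++s_out;
    }
  }

  double denom = att > 0 ? (double)att : 1.0;
  NumericVector ra(A), rb(P), rg(C);
  for (int a = 0; a < A; ++a) ra[a] = acc_a[a] / denom;
  for (int p = 0; p < P; ++p) rb[p] = acc_b[p] / denom;
  for (int c = 0; c < C; ++c) rg[c] = acc_g[c] / denom;

  return List::create(
    _["mu"] = out_mu, _["alpha"] = out_alpha, _["beta"] = out_beta,
    _["gamma"] = out_gamma, _["tau"] = out_tau,
    _["accept"] = List::create(_["alpha"] = ra, _["beta"] = rb,
                               _["gamma"] = rg, _["mu"] = acc_m / denom));
}
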