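#include <Rcpp.h>
using namespace Rcpp;

// Single-neuron-flip Metropolis-Hastings machinery for RP maximum-entropy
// models: p(x) propto exp(-E(x)), E(x) = sum_i lambda_i f_i(x),
// f_i = sigma(sum_j a_ij x_j - theta_i). Chains use R's RNG, so seeds set
// from R give bit-identical trajectories.

static inline double sigma_of(double u, double beta, bool heaviside) {
  if (heaviside) return u >= 0.0 ? 1.0 : 0.0; // boundary convention H(0)=1
  return 1.0 / (1.0 + std::exp(-beta * u));
}

struct MHState {
  const NumericMatrix &W;     // p x n
  const NumericVector &theta; // p
  const NumericVector &lam;   // p
  double beta;
  bool heaviside;
  int n, p;
  std::vector<int> x;         // current pattern
  std::vector<double> u;      // summed inputs per projection
  double E;                   // current energy

  MHState(const NumericMatrix &W_, const NumericVector &theta_,
          const NumericVector &lam_, double beta_, bool heav_,
          const std::vector<int> &init)
      : W(W_), theta(theta_), lam(lam_), beta(beta_), heaviside(heav_),
        n(W_.ncol()), p(W_.nrow()), x(init), u(p), E(0.0) {
    for (int i = 0; i < p; ++i) {
      double s = -theta[i];
      for (int j = 0; j < n; ++j)
        if (x[j]) s += W(i, j);
      u[i] = s;
      E += lam[i] * sigma_of(s, beta, heaviside);
    }
  }

  // Propose flipping neuron j at inverse temperature tempr (scales energy).
  // Returns true if accepted.
  bool try_flip(int j, double tempr) {
    double delta = x[j] ? -1.0 : 1.0;
    double dE = 0.0;
    for (int i = 0; i < p; ++i) {
      double w = W(i, j);
      if (w != 0.0)
        dE += lam[i] * (sigma_of(u[i] + delta * w, beta, heaviside) -
                        sigma_of(u[i], beta, heaviside));
    }
    if (dE <= 0.0 || unif_rand() < std::exp(-tempr * dE)) {
      for (int i = 0; i < p; ++i) {
        double w = W(i, j);
        if (w != 0.0) u[i] += delta * w;
      }
      x[j] = 1 - x[j];
      E += dE;
      return true;
    }
    return false;
  }
};

// [[Rcpp::export]]
List cpp_mh_sample(NumericMatrix W, NumericVector theta, NumericVector lambda,
                   double beta, bool heaviside, IntegerVector init,
                   int n_keep, int burn_in, int thin) {
  int n = W.ncol();
  std::vector<int> x0(init.begin(), init.end());
  MHState st(W, theta, lambda, beta, heaviside, x0);
  IntegerMatrix out(n_keep, n);
  long accepted = 0, proposed = 0;
  for (int t = 0; t < burn_in; ++t) {
    int j = (int)(unif_rand() * n); if (j == n) j = n - 1;
    accepted += st.try_flip(j, 1.0); ++proposed;
  }
  for (int k = 0; k < n_keep; ++k) {
    for (int t = 0; t < thin; ++t) {
      int j = (int)(unif_rand() * n); if (j == n) j = n - 1;
      accepted += st.try_flip(j, 1.0); ++proposed;
    }
    for (int j = 0; j < n; ++j) out(k, j) = st.x[j];
  }
  return List::create(_["samples"] = out,
                      _["accepted"] = (double)accepted,
                      _["proposed"] = (double)proposed);
}

// Advance a bank of persistent chains (rows of `states`) by n_flips
// single-neuron proposals each; used for PCD-style model expectations.
// [[Rcpp::export]]
IntegerMatrix cpp_advance_states(NumericMatrix W, NumericVector theta,
                                 NumericVector lambda, double beta,
                                 bool heaviside, IntegerMatrix states,
                                 int n_flips) {
  int m = states.nrow(), n = states.ncol();
  IntegerMatrix out(m, n);
  for (int c = 0; c < m; ++c) {
    std::vector<int> x0(n);
    for (int j = 0; j < n; ++j) x0[j] = states(c, j);
    MHState st(W, theta, lambda, beta, heaviside, x0);
    for (int t = 0; t < n_flips; ++t) {
      int j = (int)(unif_rand() * n); if (j == n) j = n - 1;
      st.try_flip(j, 1.0);
    }
    for (int j = 0; j < n; ++j) out(c, j) = st.x[j];
  }
  return out;
}

// Annealed importance sampling from the uniform model (inverse temperature
// 0) to the target (1). `betas` is the ascending ladder starting at 0 and
// ending at 1. Returns one log importance weight per chain; the target
// log-partition estimate is n*log(2) + logmeanexp(weights).
// [[Rcpp::export]]
NumericVector cpp_ais(NumericMatrix W, NumericVector theta,
                      NumericVector lambda, double beta, bool heaviside,
                      int n_chains, NumericVector betas, int sweeps) {
  int n = W.ncol();
  int K = betas.size();
  NumericVector logw(n_chains);
  for (int c = 0; c < n_chains; ++c) {
    std::vector<int> x0(n);
    for (int j = 0; j < n; ++j) x0[j] = unif_rand() < 0.5 ? 1 : 0;
    MHState st(W, theta, lambda, beta, heaviside, x0);
    double lw = 0.0;
    for (int k = 1; k < K; ++k) {
      lw += -(betas[k] - betas[k - 1]) * st.E;
      int flips = sweeps * n;
      for (int t = 0; t < flips; ++t) {
        int j = (int)(unif_rand() * n); if (j == n) j = n - 1;
        st.try_flip(j, betas[k]);
      }
    }
    logw[c] = lw;
  }
  return logw;
}
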