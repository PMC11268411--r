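#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Numerically stable softplus: log(exp(z) + 1).
static inline double softplus1(double z) {
  if (z > 0.0) return z + std::log1p(std::exp(-z));
  return std::log1p(std::exp(z));
}

// Forward pass of a two-hidden-layer network with tanh activations and a
// softplus output. X: n x J predictor rows; W1: J x L1; W2: L1 x L2;
// w3: length L2 (+1 trailing bias entry if use_bias). Returns the strictly
// positive baseline rate for every row.
// [[Rcpp::export(name = ".cpp_forward_baseline")]]
arma::vec cpp_forward_baseline(const arma::mat& X, const arma::mat& W1,
                               const arma::mat& W2, const arma::vec& w3,
                               const bool use_bias) {
  arma::mat h1 = arma::tanh(X * W1);
  arma::mat h2 = arma::tanh(h1 * W2);
  const arma::uword L2 = W2.n_cols;
  arma::vec z;
  if (use_bias) {
    z = h2 * w3.head(L2) + w3(L2);
  } else {
    z = h2 * w3;
  }
  arma::vec out(z.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) out(i) = softplus1(z(i));
  return out;
}

// Mean-preserving shrinkage of positive rates toward their grand mean:
// phi(x) = x^t * E(x) / E(x^t).
// [[Rcpp::export(name = ".cpp_regularize")]]
arma::vec cpp_regularize(const arma::vec& x, const double t_reg) {
  const double mx = arma::mean(x);
  arma::vec xt = arma::pow(x, t_reg);
  const double mxt = arma::mean(xt);
  return xt * (mx / mxt);
}

// Index of the time bin containing age a, given strictly decreasing bin
// edges (edges[0] oldest ... edges[B] = youngest, usually 0). Bins are
// half-open (edges[b+1], edges[b]]; ages <= the youngest edge fall in the
// last bin.
static inline int bin_of(double a, const arma::vec& edges) {
  const int B = edges.n_elem - 1;
  for (int b = 0; b < B; ++b) {
    if (a > edges(b + 1)) return b;
  }
  return B - 1;
}

// [[Rcpp::export(name = ".cpp_bin_of")]]
IntegerVector cpp_bin_of(const NumericVector& ages, const arma::vec& edges) {
  IntegerVector out(ages.size());
  for (int i = 0; i < ages.size(); ++i) out[i] = bin_of(ages[i], edges) + 1;
  return out;
}

// Birth-death log-likelihood per lineage (sampled birth-death process):
// extinct:  log lambda(i, s) + log mu(i, e) - int_e^s (lambda + mu) dt
// extant:   log lambda(i, s)               - int_0^s (lambda + mu) dt
// lam, mu: S x B matrices of piecewise-constant rates on the bin grid.
// [[Rcpp::export(name = ".cpp_bd_loglik")]]
arma::vec cpp_bd_loglik(const arma::vec& s, const arma::vec& e,
                        const LogicalVector& extant, const arma::mat& lam,
                        const arma::mat& mu, const arma::vec& edges) {
  const int S = lam.n_rows;
  const int B = lam.n_cols;
  arma::vec ll(S);
  for (int i = 0; i < S; ++i) {
    const int bs = bin_of(s(i), edges);
    double li = std::log(lam(i, bs));
    if (!extant[i]) {
      const int be = bin_of(e(i), edges);
      li += std::log(mu(i, be));
    }
    double integral = 0.0;
    for (int b = 0; b < B; ++b) {
      const double top = std::min(s(i), edges(b));
      const double bot = std::max(e(i), edges(b + 1));
      if (top > bot) integral += (lam(i, b) + mu(i, b)) * (top - bot);
    }
    ll(i) = li - integral;
  }
  return ll;
}

// Preservation log-likelihood per lineage under a time-variable Poisson
// process with discrete-gamma among-lineage rate multipliers, conditioned
// on observing at least one occurrence over the lifespan [e, s].
// counts: S x B occurrence counts per bin; q: length-B baseline rates;
// m: multiplier categories (equal weight).
// [[Rcpp::export(name = ".cpp_preservation_loglik")]]
arma::vec cpp_preservation_loglik(const arma::mat& counts, const arma::vec& s,
                                  const arma::vec& e, const arma::vec& q,
                                  const arma::vec& m, const arma::vec& edges) {
  const int S = counts.n_rows;
  const int B = counts.n_cols;
  const int C = m.n_elem;
  arma::vec ll(S);
  for (int i = 0; i < S; ++i) {
    // Rate-independent pieces: total expected occurrences R0 = sum q_b D_b
    // and count term sum K_b log(q_b D?) split by category multiplier.
    double R0 = 0.0;       // sum_b q_b * overlap_b
    double logq_term = 0.0; // sum_b K_b log q_b
    double Ktot = 0.0;
    for (int b = 0; b < B; ++b) {
      const double top = std::min(s(i), edges(b));
      const double bot = std::max(e(i), edges(b + 1));
      const double d = (top > bot) ? (top - bot) : 0.0;
      R0 += q(b) * d;
      const double K = counts(i, b);
      if (K > 0.0) {
        logq_term += K * std::log(q(b));
        Ktot += K;
      }
    }
    // Marginalize over categories with equal weight, in log space.
    double max_llc = -std::numeric_limits<double>::infinity();
    arma::vec llc(C);
    double p0 = 0.0; // P(K = 0) marginal
    for (int c = 0; c < C; ++c) {
      llc(c) = logq_term + Ktot * std::log(m(c)) - m(c) * R0;
      if (llc(c) > max_llc) max_llc = llc(c);
      p0 += std::exp(-m(c) * R0);
    }
    p0 /= C;
    double sum = 0.0;
    for (int c = 0; c < C; ++c) sum += std::exp(llc(c) - max_llc);
    const double lmarg = max_llc + std::log(sum / C);
    ll(i) = lmarg - std::log1p(-p0);
  }
  return ll;
}

// Layer-wise forward pieces so the sampler can cache activations: moves on
// W2/w3 do not require recomputing earlier layers.
// [[Rcpp::export(name = ".cpp_layer_tanh")]]
arma::mat cpp_layer_tanh(const arma::mat& H, const arma::mat& W) {
  return arma::tanh(H * W);
}

// [[Rcpp::export(name = ".cpp_output_softplus")]]
arma::vec cpp_output_softplus(const arma::mat& H2, const arma::vec& w3,
                              const bool use_bias) {
  const arma::uword L2 = H2.n_cols;
  arma::vec z;
  if (use_bias) z = H2 * w3.head(L2) + w3(L2);
  else z = H2 * w3;
  arma::vec out(z.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) out(i) = softplus1(z(i));
  return out;
}
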