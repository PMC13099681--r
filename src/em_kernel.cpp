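#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Per-pattern E-step over an explicit pattern matrix.
//
// U: R x I response patterns, 0/1 with missing entries coded 0
// O: R x I observation mask, 1 = observed
// f: pattern frequencies (may contain zeros)
// Returns expected counts r1/r0 (I x K), per-pattern log marginal
// likelihood, total weighted log-likelihood, and optionally the posterior
// over nodes and per-pattern score vectors (columns a_1, c_1, ..., a_I, c_I).
// [[Rcpp::export]]
List estep_cpp(const arma::mat& U, const arma::mat& O, const arma::vec& f,
               const arma::vec& a, const arma::vec& cpar,
               const arma::vec& nodes, const arma::vec& weights,
               bool keep_posterior = false, bool scores = false) {
  const arma::uword K = nodes.n_elem, I = a.n_elem, R = U.n_rows;

  arma::mat Z = nodes * a.t();          // K x I
  Z.each_row() += cpar.t();
  arma::mat logP(K, I), logQ(K, I);
  for (arma::uword i = 0; i < I; ++i) {
    for (arma::uword k = 0; k < K; ++k) {
      logP(k, i) = -log1pexp_(-Z(k, i));
      logQ(k, i) = -log1pexp_(Z(k, i));
    }
  }

  arma::mat L = U * logP.t() + (O - U) * logQ.t();  // R x K
  arma::rowvec logw = arma::log(weights).t();
  L.each_row() += logw;

  arma::vec m = arma::max(L, 1);
  arma::mat G = L;
  G.each_col() -= m;
  G = arma::exp(G);
  arma::vec s = arma::sum(G, 1);
  arma::vec ll_r = m + arma::log(s);
  G.each_col() /= s;                     // posterior over nodes, rows sum to 1

  double ll = 0.0;
  for (arma::uword r = 0; r < R; ++r) if (f(r) != 0.0) ll += f(r) * ll_r(r);

  arma::mat Gf = G;
  Gf.each_col() %= f;
  arma::mat r1 = U.t() * Gf;             // I x K
  arma::mat nmat = O.t() * Gf;
  arma::mat r0 = nmat - r1;

  List out = List::create(_["r1"] = r1, _["r0"] = r0,
                          _["loglik"] = ll, _["pattern_loglik"] = ll_r);
  if (keep_posterior) out["posterior"] = G;
  if (scores) {
    arma::mat P = arma::exp(logP);       // K x I
    arma::mat GP = G * P;                // R x I: sum_k g P
    arma::vec Ge = G * nodes;            // R
    arma::mat Pe = P;
    Pe.each_col() %= nodes;
    arma::mat GPe = G * Pe;              // R x I: sum_k g P eta
    arma::mat sc = (U - GP) % O;
    arma::mat sa = U;
    sa.each_col() %= Ge;
    sa = (sa - GPe) % O;
    arma::mat V(R, 2 * I);
    for (arma::uword i = 0; i < I; ++i) {
      V.col(2 * i) = sa.col(i);
      V.col(2 * i + 1) = sc.col(i);
    }
    out["scores"] = V;
  }
  return out;
}

// Shuffle persons (R RNG) and tabulate their pattern ids per subset block.
// id: person -> 1-based pattern id; sizes: subset sizes summing to length(id).
// Returns an n_patterns x M matrix of subset pattern frequencies — one
// epoch's random disjoint partition, without materializing index vectors.
// [[Rcpp::export]]
arma::mat shuffle_tabulate_cpp(const arma::ivec& id, int n_patterns,
                               const arma::ivec& sizes) {
  arma::ivec v = id;
  const int P = v.n_elem;
  for (int i = P - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
  arma::mat out(n_patterns, sizes.n_elem, arma::fill::zeros);
  int pos = 0;
  for (arma::uword s = 0; s < sizes.n_elem; ++s)
    for (int t = 0; t < sizes(s); ++t)
      out(v[pos++] - 1, s) += 1.0;
  return out;
}

// E-step over the complete enumeration of 2^I fully observed patterns.
//
// Pattern r (0-based) has item i answered 1 iff bit i of r is set.  The
// frequency vector f has length 2^I and may be mostly zeros (subset data).
// The per-node pattern likelihoods are built by binary doubling, so the cost
// is O(2^I * K) rather than O(2^I * K * I).  Intended for small item counts
// (the caller guards I); used both by Stage-2 subset updates on compact
// tests and by the Fisher expected-information enumeration.
// [[Rcpp::export]]
List estep_enum_cpp(const arma::vec& f, const arma::vec& a,
                    const arma::vec& cpar, const arma::vec& nodes,
                    const arma::vec& weights) {
  const arma::uword K = nodes.n_elem, I = a.n_elem;
  const arma::uword R = (arma::uword(1)) << I;

  arma::mat P(K, I), Q(K, I);
  for (arma::uword i = 0; i < I; ++i) {
    for (arma::uword k = 0; k < K; ++k) {
      double p = 1.0 / (1.0 + std::exp(-(a(i) * nodes(k) + cpar(i))));
      P(k, i) = p;
      Q(k, i) = 1.0 - p;
    }
  }

  arma::mat Lik(R, K);
  for (arma::uword k = 0; k < K; ++k) {
    double* col = Lik.colptr(k);
    col[0] = 1.0;
    arma::uword len = 1;
    for (arma::uword i = 0; i < I; ++i) {
      const double p = P(k, i), q = Q(k, i);
      for (arma::uword r = 0; r < len; ++r) {
        col[len + r] = col[r] * p;
        col[r] *= q;
      }
      len <<= 1;
    }
  }

  arma::vec pi_r = Lik * weights;        // marginal pattern probabilities
  double ll = 0.0;
  arma::vec base(R, arma::fill::zeros);  // f_r / pi_r where f_r > 0
  for (arma::uword r = 0; r < R; ++r) {
    if (f(r) != 0.0) {
      ll += f(r) * std::log(pi_r(r));
      base(r) = f(r) / pi_r(r);
    }
  }

  arma::mat r1(I, K, arma::fill::zeros);
  arma::vec nk(K);
  arma::vec gf(R);
  for (arma::uword k = 0; k < K; ++k) {
    const double wk = weights(k);
    const double* col = Lik.colptr(k);
    double* g = gf.memptr();
    for (arma::uword r = 0; r < R; ++r) g[r] = wk * col[r] * base(r);
    // tree reduction: collapsing bit i by pairwise sums leaves the higher
    // bits indexing the folded vector, and the sum of odd entries at level
    // i is exactly sum of gf over patterns with bit i set.  O(R) total.
    arma::uword len = R;
    for (arma::uword i = 0; i < I; ++i) {
      const arma::uword half = len >> 1;
      double acc = 0.0;
      for (arma::uword j = 0; j < half; ++j) {
        const double odd = g[2 * j + 1];
        acc += odd;
        g[j] = g[2 * j] + odd;
      }
      r1(i, k) = acc;
      len = half;
    }
    nk(k) = g[0];
  }

  return List::create(_["r1"] = r1, _["nk"] = nk, _["loglik"] = ll,
                      _["pi"] = pi_r);
}
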