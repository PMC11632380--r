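// Felsenstein pruning over codon states.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Core pruning pass for one rate class.
// P:       cube (n_state, n_state, n_edge), transition probabilities per edge
//          (row = parent state, col = child state), edges in postorder.
// edges:   (n_edge x 2) integer matrix of 1-based (parent, child) node
//          numbers, children before parents (ape postorder).
// states:  (n_tip x n_pat) 1-based tip states; 0 = missing data.
// rootfreq: state frequencies at the root.
// n_node:  total node count (tips + internals).
static vec prune_core(const cube& P, const imat& edges, const imat& states,
                      const vec& rootfreq, const int n_node) {
  const uword n_state = P.n_rows;
  const uword n_edge = edges.n_rows;
  const uword n_tip = states.n_rows;
  const uword n_pat = states.n_cols;

  std::vector<mat> part(n_node);
  std::vector<bool> has(n_node, false);
  std::vector<vec> scl(n_node);

  for (uword e = 0; e < n_edge; ++e) {
    const uword p = (uword)edges(e, 0) - 1;
    const uword c = (uword)edges(e, 1) - 1;
    mat contrib(n_state, n_pat);
    if (c < n_tip) {
      const mat& Pe = P.slice(e);
      for (uword j = 0; j < n_pat; ++j) {
        const int s = states(c, j);
        if (s == 0) {
          contrib.col(j).ones();  // missing: rows of P sum to 1
        } else {
          contrib.col(j) = Pe.col((uword)s - 1);
        }
      }
    } else {
      contrib = P.slice(e) * part[c];
    }
    if (!has[p]) {
      part[p] = contrib;
      has[p] = true;
      scl[p] = zeros<vec>(n_pat);
    } else {
      part[p] %= contrib;
    }
    if (c >= n_tip) scl[p] += scl[c];
    // per-pattern rescale to avoid underflow
    for (uword j = 0; j < n_pat; ++j) {
      const double m = part[p].col(j).max();
      if (m > 0 && m < 1e-100) {
        part[p].col(j) /= m;
        scl[p](j) += std::log(m);
      }
    }
  }

  const uword root = (uword)edges(n_edge - 1, 0) - 1;
  vec out(n_pat);
  for (uword j = 0; j < n_pat; ++j) {
    const double lik = dot(rootfreq, part[root].col(j));
    out(j) = std::log(std::max(lik, 1e-300)) + scl[root](j);
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_prune_loglik(const arma::cube& P,
                           const arma::imat& edges,
                           const arma::imat& states,
                           const arma::vec& rootfreq,
                           const int n_node) {
  return prune_core(P, edges, states, rootfreq, n_node);
}

// Transition matrix from a spectral decomposition of a reversible rate
// matrix: P(t) = A * diag(exp(lambda t)) * B, negatives clamped to zero.
static mat spectral_P(const mat& A, const mat& B, const vec& lam, double t) {
  if (t < 1e-8) t = 1e-8;
  mat Bs = B;
  Bs.each_col() %= exp(lam * t);
  mat P = A * Bs;
  P.transform([](double x) { return x < 0 ? 0.0 : x; });  // round-off clamp
  return P;
}

// Per-pattern log-likelihood of one omega category: builds each edge's
// transition matrix from the background or foreground decomposition and
// runs the pruning pass, all on the C++ side.
// [[Rcpp::export]]
arma::vec cpp_category_prune(const arma::mat& A_bg, const arma::mat& B_bg,
                             const arma::vec& lam_bg,
                             const arma::mat& A_fg, const arma::mat& B_fg,
                             const arma::vec& lam_fg,
                             const arma::vec& lengths,
                             const arma::uvec& fg_edge,
                             const arma::imat& edges,
                             const arma::imat& states,
                             const arma::vec& rootfreq,
                             const int n_node) {
  const uword n_state = A_bg.n_rows;
  const uword n_edge = edges.n_rows;
  cube P(n_state, n_state, n_edge);
  for (uword e = 0; e < n_edge; ++e) {
    P.slice(e) = fg_edge(e)
      ? spectral_P(A_fg, B_fg, lam_fg, lengths(e))
      : spectral_P(A_bg, B_bg, lam_bg, lengths(e));
  }
  return prune_core(P, edges, states, rootfreq, n_node);
}
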