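#include <RcppArmadillo.h>
#include <map>
#include <tuple>
// [[Rcpp::depends(RcppArmadillo)]]

// Felsenstein pruning over one site class.
//
// tip_states: ntip x npat, entries in 1..nstate, 0 = missing/ambiguous
// edges:      nedge x 2 (parent, child), 1-based ape node ids in postorder
//             (every child row precedes the row where that node is a parent)
// blens:      per-edge branch lengths, expected substitutions per site/codon
// A, Ainv, lambda: eigensystem(s) of the reversible generator(s), so that
//             P(t) = A diag(exp(lambda t)) Ainv; slice e of the cubes is the
//             eigensystem used by edges with edge_eig == e (1-based)
// pi:         root (equilibrium) frequencies
//
// Returns per-pattern likelihoods (not logged).
// [[Rcpp::export]]
arma::vec site_likelihoods_cpp(const arma::imat& tip_states,
                               const arma::imat& edges,
                               const arma::vec& blens,
                               const arma::cube& A,
                               const arma::cube& Ainv,
                               const arma::mat& lambda,
                               const arma::ivec& edge_eig,
                               const arma::vec& pi,
                               const int n_nodes,
                               const int root) {
  const int nstate = A.n_rows;
  const int ntip = tip_states.n_rows;
  const int npat = tip_states.n_cols;
  const int nedge = edges.n_rows;

  arma::cube L(nstate, npat, n_nodes, arma::fill::ones);
  for (int i = 0; i < ntip; ++i) {
    for (int j = 0; j < npat; ++j) {
      const int s = tip_states(i, j);
      if (s > 0) {
        L.slice(i).col(j).zeros();
        L(s - 1, j, i) = 1.0;
      }
    }
  }

  for (int e = 0; e < nedge; ++e) {
    const int parent = edges(e, 0) - 1;
    const int child = edges(e, 1) - 1;
    const int k = edge_eig(e) - 1;
    arma::mat P = A.slice(k) *
      arma::diagmat(arma::exp(lambda.col(k) * blens(e))) * Ainv.slice(k);
    // numerical round-off can leave tiny negatives in P
    P.clamp(0.0, arma::datum::inf);
    L.slice(parent) %= P * L.slice(child);
  }

  arma::vec out(npat);
  const arma::mat& R = L.slice(root - 1);
  for (int j = 0; j < npat; ++j) out(j) = arma::dot(pi, R.col(j));
  return out;
}

// Mixture version: all site classes in one call. Transition matrices are
// memoized on (eigensystem, edge, rate), so classes sharing a generator on
// a branch (e.g. background classes of the branch-site model, or gamma
// categories sharing the GTR eigensystem) reuse the same P.
//
// edge_eig:    nedge x nclass, 1-based eigensystem slice per edge/class
// class_rate:  branch-length multiplier per class (gamma categories)
// class_prob:  mixture weight per class
// root_freq:   nstate x nclass root frequencies
// [[Rcpp::export]]
arma::vec mixture_site_liks_cpp(const arma::imat& tip_states,
                                const arma::imat& edges,
                                const arma::vec& blens,
                                const arma::cube& A,
                                const arma::cube& Ainv,
                                const arma::mat& lambda,
                                const arma::imat& edge_eig,
                                const arma::vec& class_rate,
                                const arma::vec& class_prob,
                                const arma::mat& root_freq,
                                const int n_nodes,
                                const int root) {
  const int nstate = A.n_rows;
  const int ntip = tip_states.n_rows;
  const int npat = tip_states.n_cols;
  const int nedge = edges.n_rows;
  const int nclass = class_prob.n_elem;

  // tip partials shared by all classes
  arma::cube Ltip(nstate, npat, ntip, arma::fill::ones);
  for (int i = 0; i < ntip; ++i) {
    for (int j = 0; j < npat; ++j) {
      const int s = tip_states(i, j);
      if (s > 0) {
        Ltip.slice(i).col(j).zeros();
        Ltip(s - 1, j, i) = 1.0;
      }
    }
  }

  std::map<std::tuple<int, int, double>, arma::mat> pcache;
  arma::vec out(npat, arma::fill::zeros);
  arma::cube L(nstate, npat, n_nodes);

  for (int c = 0; c < nclass; ++c) {
    L.ones();
    L.slices(0, ntip - 1) = Ltip;
    const double rate = class_rate(c);
    for (int e = 0; e < nedge; ++e) {
      const int parent = edges(e, 0) - 1;
      const int child = edges(e, 1) - 1;
      const int k = edge_eig(e, c) - 1;
      const std::tuple<int, int, double> key(k, e, rate);
      auto it = pcache.find(key);
      if (it == pcache.end()) {
        arma::mat P = A.slice(k) *
          arma::diagmat(arma::exp(lambda.col(k) * (blens(e) * rate))) *
          Ainv.slice(k);
        P.clamp(0.0, arma::datum::inf);
        it = pcache.emplace(key, std::move(P)).first;
      }
      L.slice(parent) %= it->second * L.slice(child);
    }
    const arma::mat& R = L.slice(root - 1);
    const arma::vec piC = root_freq.col(c);
    for (int j = 0; j < npat; ++j) {
      out(j) += class_prob(c) * arma::dot(piC, R.col(j));
    }
  }
  return out;
}
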