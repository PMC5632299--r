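// Felsenstein pruning over codon states with per-edge rate-class structure.
// The hot loop of every likelihood evaluation: one dense 61 x npat product per
// internal edge, a column gather per tip edge, with per-node rescaling to
// avoid underflow on deep trees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build P(t) = U1 * diag(exp(values * t)) * U2 from a reversible
// eigendecomposition; clamps round-off negatives and renormalizes rows.
static arma::mat pmat_from_eig(const arma::mat& U1, const arma::mat& U2,
                               const arma::vec& values, double t) {
  arma::mat P = U1 * (arma::diagmat(arma::exp(values * t)) * U2);
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  arma::vec rs = arma::sum(P, 1);
  P.each_col() /= rs;
  return P;
}

// patterns: ntaxa x npat, entries 1..nstate or 0 = missing (partial of ones)
// edges:    nedge x 2 (parent, child), 1-based node ids, postorder
//           (every child edge appears before its parent's edge)
// lens:     edge lengths
// class_eig: nedge x nclass matrix, 1-based index into `eig` selecting the
//           rate system (omega class) for that edge within each site class
// eig:      list of lists with elements U1, U2, values
// pi:       root state frequencies
// Returns npat x nclass matrix of per-site-pattern log-likelihoods.
// [[Rcpp::export(name = ".prune_loglik")]]
arma::mat prune_loglik(const arma::imat& patterns,
                       const arma::imat& edges,
                       const arma::vec& lens,
                       const arma::imat& class_eig,
                       List eig,
                       const arma::vec& pi,
                       int nnode_total) {
  const int ntaxa = patterns.n_rows;
  const int npat = patterns.n_cols;
  const int nedge = edges.n_rows;
  const int nclass = class_eig.n_cols;
  const int nstate = pi.n_elem;
  const int neig = eig.size();

  // unpack eigen systems once
  std::vector<arma::mat> U1(neig), U2(neig);
  std::vector<arma::vec> vals(neig);
  for (int k = 0; k < neig; ++k) {
    List ek = eig[k];
    U1[k] = as<arma::mat>(ek["U1"]);
    U2[k] = as<arma::mat>(ek["U2"]);
    vals[k] = as<arma::vec>(ek["values"]);
  }

  // P matrices cached per (edge, eigen system): shared across site classes
  std::vector<std::vector<int>> pkey(nedge);
  std::vector<std::vector<arma::mat>> pval(nedge);

  arma::mat out(npat, nclass);
  const int root = edges(nedge - 1, 0) - 1;

  for (int c = 0; c < nclass; ++c) {
    std::vector<arma::mat> partial(nnode_total);
    std::vector<bool> touched(nnode_total, false);
    arma::rowvec logscale(npat, arma::fill::zeros);

    for (int e = 0; e < nedge; ++e) {
      const int parent = edges(e, 0) - 1;
      const int child = edges(e, 1) - 1;
      const int ei = class_eig(e, c) - 1;

      const arma::mat* P = nullptr;
      for (size_t k = 0; k < pkey[e].size(); ++k)
        if (pkey[e][k] == ei) { P = &pval[e][k]; break; }
      if (!P) {
        pkey[e].push_back(ei);
        pval[e].push_back(pmat_from_eig(U1[ei], U2[ei], vals[ei], lens(e)));
        P = &pval[e].back();
      }

      arma::mat contrib(nstate, npat);
      if (child < ntaxa) {
        for (int p = 0; p < npat; ++p) {
          const int st = patterns(child, p);
          if (st > 0) contrib.col(p) = P->col(st - 1);
          else contrib.col(p).ones();
        }
      } else {
        // child is complete (postorder); rescale before propagating
        arma::mat& L = partial[child];
        arma::rowvec mx = arma::max(L, 0);
        mx.transform([](double v) { return v <= 0.0 ? 1.0 : v; });
        L.each_row() /= mx;
        logscale += arma::log(mx);
        contrib = (*P) * L;
      }

      if (!touched[parent]) {
        partial[parent] = contrib;
        touched[parent] = true;
      } else {
        partial[parent] %= contrib;
      }
    }

    arma::rowvec site = pi.t() * partial[root];
    for (int p = 0; p < npat; ++p)
      out(p, c) = std::log(site(p)) + logscale(p);
  }
  return out;
}
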