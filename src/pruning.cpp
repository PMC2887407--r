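// Scaled Felsenstein pruning over codon site patterns.
//
// States are 1-based indices into the 61 sense codons; 0 marks a missing
// codon (gap or N), whose conditional likelihood is 1 for every state.
// Edges arrive in postorder; per-pattern log scale factors keep the
// partials in range on long alignments.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int NS = 61;

// conditional likelihood flowing from child `ch` through its branch with
// transition matrix P (NS x NS): P %*% D for an internal child, column
// selection for a tip.
static arma::mat child_flow(const arma::mat& P, int ch, int nTip,
                            const IntegerMatrix& pat,
                            const std::vector<arma::mat>& D, int npat) {
  if (ch > nTip) return P * D[ch - 1];
  arma::mat G(NS, npat);
  for (int h = 0; h < npat; ++h) {
    int s = pat(h, ch - 1);
    if (s == 0)
      G.col(h).ones();
    else
      G.col(h) = P.col(s - 1);
  }
  return G;
}

struct DownPass {
  std::vector<arma::mat> D;
  std::vector<arma::rowvec> dls;
};

static DownPass down_pass(const IntegerMatrix& edge, int nTip, int nNode,
                          const List& Plist, const IntegerMatrix& pat) {
  int npat = pat.nrow(), nE = edge.nrow();
  DownPass dp;
  dp.D.resize(nNode);
  dp.dls.assign(nNode, arma::rowvec(npat, arma::fill::zeros));
  std::vector<arma::mat> Ps(nE);
  for (int e = 0; e < nE; ++e) Ps[e] = as<arma::mat>(Plist[e]);

  int e = 0;
  while (e < nE) {
    int nd = edge(e, 0);
    arma::mat acc;
    arma::rowvec ls(npat, arma::fill::zeros);
    bool first = true;
    while (e < nE && edge(e, 0) == nd) {
      int ch = edge(e, 1);
      arma::mat G = child_flow(Ps[e], ch, nTip, pat, dp.D, npat);
      if (first) { acc = G; first = false; }
      else acc %= G;
      if (ch > nTip) ls += dp.dls[ch - 1];
      ++e;
    }
    arma::rowvec sc = arma::sum(acc, 0);
    sc.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
    acc.each_row() /= sc;
    dp.D[nd - 1] = acc;
    dp.dls[nd - 1] = ls + arma::log(sc);
  }
  return dp;
}

// Per-pattern log-likelihood: postorder edges, tip states, root frequencies.
// [[Rcpp::export]]
NumericVector cpp_prune_loglik(IntegerMatrix edge, int nTip, int nNode,
                               List Plist, IntegerMatrix pat,
                               NumericVector pi, int root) {
  int npat = pat.nrow();
  DownPass dp = down_pass(edge, nTip, nNode, Plist, pat);
  arma::vec piv = as<arma::vec>(pi);
  arma::rowvec L = piv.t() * dp.D[root - 1];
  L.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
  arma::rowvec out = arma::log(L) + dp.dls[root - 1];
  return NumericVector(out.begin(), out.end());
}

// Partials framing one edge: the conditional likelihood D at its child end
// (with log scales) and the outside-likelihood U at its parent end, so the
// edge's length can be optimised with everything else fixed:
//   lnl(t) = sum_h w_h [ log(sum_ij U_ih P_ij(t) D_jh) + uls_h + dls_h ].
// [[Rcpp::export]]
List cpp_edge_partials(IntegerMatrix edge, int nTip, int nNode,
                       List Plist, IntegerMatrix pat,
                       NumericVector pi, int root, int target) {
  int npat = pat.nrow(), nE = edge.nrow();
  DownPass dp = down_pass(edge, nTip, nNode, Plist, pat);
  std::vector<arma::mat> Ps(nE);
  for (int e = 0; e < nE; ++e) Ps[e] = as<arma::mat>(Plist[e]);
  arma::vec piv = as<arma::vec>(pi);

  // upward partials, preorder (reverse postorder); only edges on the path
  // from the root to `target` are actually needed, but the full pass is
  // cheap relative to the downstream 1-D optimisation it enables.
  std::vector<arma::mat> U(nE);
  std::vector<arma::rowvec> uls(nE);
  std::vector<int> edge_above(nNode, -1);
  for (int e = 0; e < nE; ++e) edge_above[edge(e, 1) - 1] = e;

  for (int e = nE - 1; e >= 0; --e) {
    int p = edge(e, 0);
    arma::mat acc;
    arma::rowvec ls(npat, arma::fill::zeros);
    if (p == root) {
      acc = arma::repmat(piv, 1, npat);
    } else {
      int pe = edge_above[p - 1];
      acc = Ps[pe].t() * U[pe];
      ls = uls[pe];
    }
    for (int s = 0; s < nE; ++s) {
      if (s == e || edge(s, 0) != p) continue;
      int ch = edge(s, 1);
      acc %= child_flow(Ps[s], ch, nTip, pat, dp.D, npat);
      if (ch > nTip) ls += dp.dls[ch - 1];
    }
    arma::rowvec sc = arma::sum(acc, 0);
    sc.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
    acc.each_row() /= sc;
    U[e] = acc;
    uls[e] = ls + arma::log(sc);
  }

  int v = edge(target - 1, 1);
  arma::mat Dv;
  arma::rowvec dls_v(npat, arma::fill::zeros);
  bool v_tip = v <= nTip;
  if (!v_tip) {
    Dv = dp.D[v - 1];
    dls_v = dp.dls[v - 1];
  }
  return List::create(
    _["U"] = wrap(U[target - 1]),
    _["uls"] = NumericVector(uls[target - 1].begin(), uls[target - 1].end()),
    _["D"] = v_tip ? R_NilValue : wrap(Dv),
    _["dls"] = NumericVector(dls_v.begin(), dls_v.end()));
}
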