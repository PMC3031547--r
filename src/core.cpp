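// Numerical core: reversible-model eigendecomposition, Felsenstein pruning
// over a mixture class (per-edge substitution system), and affine-gap
// profile-profile alignment (Gotoh).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Eigendecomposition of a reversible rate matrix Q with stationary
// distribution pi, via the symmetrized matrix B = D^{1/2} Q D^{-1/2}.
// Q = U diag(lambda) Uinv with U = D^{-1/2} V, Uinv = V' D^{1/2}.
// [[Rcpp::export(name = ".rev_eigen_cpp")]]
List rev_eigen_cpp(const arma::mat& Q, const arma::vec& pi) {
  arma::vec sq = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= sq;        // D^{1/2} Q
  B.each_row() /= sq.t();    // ... D^{-1/2}
  B = 0.5 * (B + B.t());     // symmetrize against round-off
  arma::vec lam;
  arma::mat V;
  arma::eig_sym(lam, V, B);
  arma::mat U = V;
  U.each_col() /= sq;
  arma::mat Uinv = V.t();
  Uinv.each_row() %= sq.t();
  return List::create(_["U"] = U, _["lambda"] = lam, _["Uinv"] = Uinv);
}

// Transition probability matrix P(t) = U diag(exp(lambda t)) Uinv, with
// small negatives from round-off clamped and rows renormalized.
// [[Rcpp::export(name = ".pmat_cpp")]]
arma::mat pmat_cpp(const arma::mat& U, const arma::vec& lambda,
                   const arma::mat& Uinv, double t) {
  arma::mat P = U * arma::diagmat(arma::exp(lambda * t)) * Uinv;
  P.elem(arma::find(P < 0)).zeros();
  arma::vec rs = arma::sum(P, 1);
  P.each_col() /= rs;
  return P;
}

// Per-pattern log-likelihood by pruning for ONE mixture class.
//
// edge:      E x 2 integer matrix (ape convention, 1-based node ids,
//            tips 1..nTip, root nTip+1), in postorder (children before
//            parents).
// edgeLen:   branch lengths (expected events per site at class rate 1).
// edgeSys:   1-based index into the eigen-system lists, per edge (allows
//            branch-heterogeneous omega classes).
// tipStates: nTip x npat integer matrix, 1-based observed state, 0 = missing
//            (gap/ambiguity -> all-ones partial).
// pi:        root frequencies.
// scale:     global rate multiplier applied to every edge length.
// [[Rcpp::export(name = ".prune_siteloglik_cpp")]]
arma::rowvec prune_siteloglik_cpp(const arma::imat& edge,
                                  const arma::vec& edgeLen,
                                  int nTip,
                                  const List& Ulist,
                                  const List& lamlist,
                                  const List& Uinvlist,
                                  const arma::ivec& edgeSys,
                                  const arma::imat& tipStates,
                                  const arma::vec& pi,
                                  double scale) {
  const int E = edge.n_rows;
  const int S = pi.n_elem;
  const int npat = tipStates.n_cols;
  int nNode = nTip;
  for (int e = 0; e < E; ++e) {
    nNode = std::max(nNode, std::max(edge(e, 0), edge(e, 1)));
  }

  std::vector<arma::mat> partial(nNode + 1);
  std::vector<bool> touched(nNode + 1, false);
  arma::rowvec logscale(npat, arma::fill::zeros);

  // Cache eigen systems as arma objects once.
  const int nsys = Ulist.size();
  std::vector<arma::mat> Us(nsys), Uinvs(nsys);
  std::vector<arma::vec> lams(nsys);
  for (int s = 0; s < nsys; ++s) {
    Us[s] = as<arma::mat>(Ulist[s]);
    Uinvs[s] = as<arma::mat>(Uinvlist[s]);
    lams[s] = as<arma::vec>(lamlist[s]);
  }

  for (int e = 0; e < E; ++e) {
    const int par = edge(e, 0);
    const int chi = edge(e, 1);
    const int sys = edgeSys(e) - 1;
    arma::mat P = Us[sys] *
      arma::diagmat(arma::exp(lams[sys] * (edgeLen(e) * scale))) * Uinvs[sys];
    P.elem(arma::find(P < 0)).zeros();

    arma::mat down(S, npat);
    if (chi <= nTip) {
      // tip partial: unit vector or ones; down = P * L equals column of P
      for (int p = 0; p < npat; ++p) {
        const int st = tipStates(chi - 1, p);
        if (st == 0) {
          down.col(p) = arma::sum(P, 1);  // missing: sum_j P_ij
        } else {
          down.col(p) = P.col(st - 1);
        }
      }
    } else {
      down = P * partial[chi];
    }
    if (!touched[par]) {
      partial[par] = down;
      touched[par] = true;
    } else {
      partial[par] %= down;
      // rescale to avoid underflow
      arma::rowvec mx = arma::max(partial[par], 0);
      mx.elem(arma::find(mx <= 0)).ones();
      partial[par].each_row() /= mx;
      logscale += arma::log(mx);
    }
  }

  const int root = nTip + 1;
  arma::rowvec lik = pi.t() * partial[root];
  return arma::log(lik) + logscale;
}

// Global affine-gap alignment of two profiles given the column-pair score
// matrix colScore (La x Lb). A gap run of length k costs open + k * extend.
// Traceback preference on ties: aligned column, then gap in the first
// profile (consume b), then gap in the second (consume a).
// Returns 0-based column maps (0 = gap) and the optimal score.
// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(const arma::mat& colScore, double gapOpen,
                     double gapExtend) {
  const int La = colScore.n_rows;
  const int Lb = colScore.n_cols;
  const double NEG = -1e300;
  arma::mat M(La + 1, Lb + 1), X(La + 1, Lb + 1), Y(La + 1, Lb + 1);
  // X: gap in b (consumes a, vertical); Y: gap in a (consumes b, horizontal)
  M.fill(NEG); X.fill(NEG); Y.fill(NEG);
  M(0, 0) = 0.0;
  for (int i = 1; i <= La; ++i)
    X(i, 0) = gapOpen + i * gapExtend;
  for (int j = 1; j <= Lb; ++j)
    Y(0, j) = gapOpen + j * gapExtend;

  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      double best = std::max(M(i - 1, j - 1),
                    std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = best + colScore(i - 1, j - 1);
      X(i, j) = std::max(std::max(M(i - 1, j) + gapOpen + gapExtend,
                                  X(i - 1, j) + gapExtend),
                         Y(i - 1, j) + gapOpen + gapExtend);
      Y(i, j) = std::max(std::max(M(i, j - 1) + gapOpen + gapExtend,
                                  Y(i, j - 1) + gapExtend),
                         X(i, j - 1) + gapOpen + gapExtend);
    }
  }

  double score = std::max(M(La, Lb), std::max(X(La, Lb), Y(La, Lb)));
  // state: 0 = M, 1 = X (gap in b), 2 = Y (gap in a); preference M > Y > X?
  // Declared preference: aligned > gap-in-first > gap-in-second. The first
  // profile is 'a' (rows); a gap IN a means consuming b, i.e. state Y.
  int i = La, j = Lb, state;
  if (M(La, Lb) >= score) state = 0;
  else if (Y(La, Lb) >= score) state = 2;
  else state = 1;

  std::vector<int> ai, bi;  // reversed
  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      const double tgt = M(i, j) - colScore(i - 1, j - 1);
      --i; --j;
      if (M(i, j) >= tgt - 1e-9) state = 0;
      else if (Y(i, j) >= tgt - 1e-9) state = 2;
      else state = 1;
    } else if (state == 1) {  // gap in b, consume a
      ai.push_back(i); bi.push_back(0);
      const double cur = X(i, j);
      --i;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) + gapOpen + gapExtend - cur) < 1e-9 && i >= 0 && j >= 0 && M(i,j) > NEG/2) state = 0;
      else if (std::abs(X(i, j) + gapExtend - cur) < 1e-9) state = 1;
      else state = 2;
    } else {  // gap in a, consume b
      ai.push_back(0); bi.push_back(j);
      const double cur = Y(i, j);
      --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) + gapOpen + gapExtend - cur) < 1e-9 && M(i,j) > NEG/2) state = 0;
      else if (std::abs(Y(i, j) + gapExtend - cur) < 1e-9) state = 2;
      else state = 1;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = score);
}
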